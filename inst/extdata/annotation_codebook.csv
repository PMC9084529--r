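column,file,type,category,description
trial_id,annotations,text,key,Unified trial identifier the annotation belongs to
observational,annotations,logical,context,Study is observational; masking and intervention categories become not applicable and the title intervention element is waived
open_label,annotations,logical,context,Trial is open label; masking becomes not applicable
title_has_intervention,annotations,logical,title,Title names the intervention (leave empty when waived)
title_has_indication,annotations,logical,title,Title names the indication
title_has_outcome,annotations,logical,title,Title names an outcome
title_outcome_is_primary,annotations,logical,title,The titled outcome is one of the primary outcomes
design_adequate,annotations,logical,design,Design description adequate (not insufficient)
design_consistent,annotations,logical,design,No internal inconsistencies between registered design fields and title
sample_size_given,annotations,logical,sample_size,A (target) sample size is registered
masking_who_described,annotations,logical,masking,Who is blinded is described ('double blind' suffices)
masking_party_given,annotations,logical,masking,The party responsible for blinding is also given
inclusion_criteria_clear,annotations,logical,inclusion,Criteria by which patients are screened are clear
inclusion_all_measured,annotations,logical,inclusion,Diagnoses and accompanying measures given for all key criteria
intervention_insufficient,annotations,logical,intervention,Intervention information insufficient (forces 0)
intervention_type_given,annotations,logical,intervention,Active ingredient or intervention type given
intervention_detail_given,annotations,logical,intervention,Dosage or detailed description also given
funding,annotations,unrated,funding,Category represented in the codebook but carries no rated criteria
contact_details,annotations,unrated,contact_details,Category represented but not rated; contacts feed the survey instead
result_data,annotations,unrated,result_data,Category represented but not rated; replaced by the manual article search
trial_id,outcomes,text,key,Trial the outcome belongs to
role,outcomes,enum,outcomes,primary or secondary
insufficient,outcomes,logical,outcomes,Outcome information insufficient (forces 0)
has_type,outcomes,logical,outcomes,Type of outcome given
has_measure,outcomes,logical,outcomes,A measure is named (e.g. a validated instrument)
has_timeframe,outcomes,logical,outcomes,A time frame is given
has_metric,outcomes,logical,outcomes,A metric is given (e.g. change from baseline or end value)
has_aggregation,outcomes,logical,outcomes,An aggregation method is given (e.g. mean or proportion of patients)
is_survival,outcomes,logical,outcomes,Outcome is survival; missing aggregation method is not penalized
metric_inferable_or_moot,outcomes,logical,outcomes,Metric inferable from other elements or no metric sensible
similar_to_primary,outcomes,logical,outcomes,Secondary outcome highly similar to a primary outcome (skipped where possible)
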