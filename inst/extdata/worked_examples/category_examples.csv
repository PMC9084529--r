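trial_id,category,observational,open_label,title_has_intervention,title_has_indication,title_has_outcome,title_outcome_is_primary,design_adequate,design_consistent,sample_size_given,masking_who_described,masking_party_given,inclusion_criteria_clear,inclusion_all_measured,intervention_insufficient,intervention_type_given,intervention_detail_given,comment
NCT00044915,title,FALSE,FALSE,TRUE,TRUE,TRUE,TRUE,,,,,,,,,,,"randomized double-blind placebo-controlled trial of repinotan in acute ischemic stroke: intervention, indication and (primary) outcomes all titled"
DRKS00004434,title,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,,,,,,,,,,,"lung CT segmentation title names intervention and indication but no outcome"
EUCTR2006-001433-17,design,FALSE,FALSE,,,,,TRUE,FALSE,,,,,,,,,"parallel and double-blind per title but registered non-parallel and open: internal inconsistency"
NCT02320045,inclusion,FALSE,FALSE,,,,,,,,,,TRUE,TRUE,,,,"BMI range and eGFR bands with units: measures for all key criteria"
NCT01374399,inclusion,FALSE,FALSE,,,,,,,,,,TRUE,FALSE,,,,"indication given but no description of how the diagnosis is arrived at"
NCT01458574,inclusion,FALSE,FALSE,,,,,,,,,,FALSE,FALSE,,,,"criteria only by reference to other studies' unstated entry and response criteria"
EUCTR2007-000010-36,intervention,FALSE,FALSE,,,,,,,,,,,,FALSE,TRUE,TRUE,"aclidinium bromide, LAS34273, 200 microgram(s): active ingredient and dosage"
NCT03429543,intervention,FALSE,FALSE,,,,,,,,,,,,FALSE,TRUE,FALSE,"empagliflozin titration regimen with dosage missing or undefined"
NCT01709812,intervention,FALSE,FALSE,,,,,,,,,,,,TRUE,FALSE,FALSE,"individualized patient support with compliance supporting tools: unclear"
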