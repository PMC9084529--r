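trial_id,role,insufficient,has_type,has_measure,has_timeframe,has_metric,has_aggregation,is_survival,metric_inferable_or_moot,similar_to_primary,comment
NCT00690898,primary,FALSE,TRUE,TRUE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,"complete: tumour-volume reduction (type), MRI (measure), week 1 to week 48 (time frame), change from baseline volume (metric), percentage of patients (aggregation)"
ISRCTN43578978,primary,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,FALSE,"agitation (type) on the Cohen-Mansfield Agitation Inventory (measure) with registered time frame; metric moot for the scale endpoint; aggregation method (e.g. mean) missing"
NCT01973179,primary,FALSE,TRUE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,"late toxicity (type) at 24 months (time frame) measured from first day of treatment (metric); no definition of toxicity (measure) and no aggregation method"
NCT01012921,primary,FALSE,FALSE,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,"bone fill at 6 months (time frame) as change from baseline (metric); no type of outcome, no unit of measurement, no aggregation method"
DRKS00000025,primary,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,"drug-use documentation goal: no aggregation method, no time frame, no type of outcome or measure; only the metric element is satisfied (moot for pure documentation)"
NCT00240214,primary,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,"outcome section missing entirely"
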