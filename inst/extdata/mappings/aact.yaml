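# Column mapping for AACT (Aggregate Analysis of ClinicalTrials.gov)
# pipe-delimited `studies`-style export. Versioned config: edit the `fields`
# block if your snapshot uses different headers.
dialect: AACT
schema_version: "2021-flat-1"
delimiter: "|"
registry: "ClinicalTrials.gov"
registry_from: ~
mandatory: [nct_id]
fields:
  record_id: nct_id
  title: official_title
  registration_date: study_first_submitted_date
  start_date: start_date
  study_type: study_type
  sample_size: enrollment
  secondary_ids: secondary_ids
  sponsor_names: sponsor_name
  contact_emails: contact_email
  recruiting_countries: countries
date_formats: ["ymd", "ym", "y"]
list_separator: ";"
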