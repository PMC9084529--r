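# Column mapping for the DRKS (German Clinical Trials Register) CSV export.
dialect: DRKS
schema_version: "2021-1"
delimiter: ","
registry: "DRKS"
registry_from: ~
mandatory: [drksId]
fields:
  record_id: drksId
  title: title
  registration_date: created_at
  start_date: start_date
  study_type: studyType
  sample_size: targetSize
  secondary_ids: secondaryIds
  sponsor_names: address.affiliation
  contact_emails: email
  recruiting_countries: recruitmentCountries
date_formats: ["dmy_dot", "ymd", "my_dot", "ym", "y"]
list_separator: ";"
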