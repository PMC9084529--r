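# Column mapping for the WHO ICTRP full CSV export (comma, quoted fields).
# ICTRP aggregates partner registries; the source registry is read from
# Source_Register and recorded as "ICTRP-partner:<name>". ICTRP dates are
# day-first.
dialect: ICTRP
schema_version: "2021-1"
delimiter: ","
registry: ~
registry_from: Source_Register
registry_prefix: "ICTRP-partner:"
mandatory: [TrialID]
fields:
  record_id: TrialID
  title: Public_title
  registration_date: Date_registration
  start_date: Date_enrollment
  study_type: Study_type
  sample_size: Target_size
  secondary_ids: Secondary_IDs
  sponsor_names: Primary_sponsor
  contact_emails: Scientific_Contact_email
  recruiting_countries: Countries
date_formats: ["dmy_slash", "ymd", "my_slash", "ym", "y"]
list_separator: ";"
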