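{
  "schema": "dcekit/attribute_space/1",
  "attributes": [
    {"name": "cost", "levels": ["Free", "$5", "$10"]},
    {"name": "speed", "levels": ["Instant", "1-5 min", "More than 5 min"]},
    {"name": "accuracy", "levels": ["60-69%", "70-79%", "80-89%", ">90%"]},
    {"name": "anonymity", "levels": ["No login", "Email login", "Two-factor login"]},
    {"name": "app_type", "levels": ["Web", "Mobile"]},
    {"name": "services", "levels": ["Report only", "Report + Helpline", "Report + Helpline + Booking", "Report + Pathology form"]}
  ]
}
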