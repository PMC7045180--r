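[
  {"activity": "patient_delay",      "family": "lognormal", "median": 41, "q1": 5,  "q3": 130, "cap": null},
  {"activity": "responder_response", "family": "lognormal", "median": 9,  "q1": 7,  "q3": 12,  "cap": null},
  {"activity": "gp_consult",         "family": "lognormal", "median": 30, "q1": 15, "q3": 60,  "cap": null},
  {"activity": "on_scene",           "family": "lognormal", "median": 20, "q1": 15, "q3": 25,  "cap": null},
  {"activity": "transport",          "family": "lognormal", "median": 17, "q1": 9,  "q3": 22,  "cap": null},
  {"activity": "self_transport",     "family": "lognormal", "median": 17, "q1": 9,  "q3": 22,  "cap": null},
  {"activity": "dtn",                "family": "lognormal", "median": 35, "q1": 25, "q3": 45,  "cap": null}
]
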