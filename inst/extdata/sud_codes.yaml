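# Illustrative stand-ins for the SUD diagnostic-code and OAT drug-code
# registries (the provincial lists are not public). Diagnostic codes follow
# the ICD-9 substance-disorder families; drug codes match the synthetic
# formulary shipped with the generator. Replace both for real extracts.
sud_diagnostic_codes: ["291", "292", "303", "304", "305"]
oat_drug_codes: ["MET-OAT", "BUP-NAL"]
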