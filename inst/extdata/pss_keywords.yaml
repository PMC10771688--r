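# Illustrative PSS case-finding lexicon. The provincial keyword lists are not
# public; these defaults mirror their structure (keywords over the
# directions-for-use text crossed with an eligible medication-class set, in a
# sensitive and a specific tier) and are meant to be edited for any real
# application. The specific tier must be a subset of the sensitive tier.
sensitive:
  patterns:
    - "risk mitigation"
    - "rmg"
    - "safer supply"
    - "pandemic"
    - "covid"
    - "witnessed daily dispense"
  classes: [opioid, stimulant, benzodiazepine]
specific:
  patterns:
    - "risk mitigation"
    - "rmg"
  classes: [opioid, stimulant, benzodiazepine]
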