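default: UV2
rules:
- when:
    ptc:
      eq: yes
  class: Pathogenic
- when:
    minigene_result:
      eq: deleterious
  class: UV4
- when:
    splice_delta:
      ge: 0.8
  class: UV4
- when:
    control_af:
      gt: 0.01
  class: Neutral
- when:
    patient_af:
      gt: 0.01
    missense_score:
      ge: 0.8
  class: UV4
- when:
    missense_score:
      ge: 0.8
  class: UV3
- when:
    patient_af:
      gt: 0.01
  class: UV3
- when:
    splice_delta:
      ge: 0.3
  class: UV2
- when:
    missense_score:
      ge: 0.5
  class: UV2
- when:
    missense_score:
      lt: 0.5
  class: UV1
- when:
    splice_delta:
      lt: 0.3
  class: UV1
- when:
    control_af:
      gt: 0.001
  class: UV1
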