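overhang_forward: TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
overhang_reverse: GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG
annealing_temp_C: 62.0
cycles: 25.0
primers:
- name: For_Mu
  sequence: CCTTTTGCATAAGGGTTTTTCAAG
  direction: forward
  family: Mytilidae
  concentration_uM: 0.4
- name: Rev1_Mu
  sequence: CGAATAGTATCTAGCCGCCATTC
  direction: reverse
  family: Mytilidae
  concentration_uM: 0.2
- name: Rev2_Mu
  sequence: GCAAATAGCATATCACTTTCACCTC
  direction: reverse
  family: Mytilidae
  concentration_uM: 0.2
- name: For_Sc
  sequence: TGCTAAGGTAGCTAAATTATGGCC
  direction: forward
  family: Pectinidae
  concentration_uM: 0.2
- name: Rev_Sc
  sequence: CTTCACGGGGTCTTCTCGTC
  direction: reverse
  family: Pectinidae
  concentration_uM: 0.2
- name: For_Oy
  sequence: GGTAGCGAAATTCCTTGCCTT
  direction: forward
  family: Ostreidae
  concentration_uM: 0.2
- name: Rev_Oy
  sequence: AAAGTTGCACGGGGTCTT
  direction: reverse
  family: Ostreidae
  concentration_uM: 0.2
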