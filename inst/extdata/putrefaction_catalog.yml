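pathways:
- pathway_id: histidine_degradation
  name: Histidine degradation (histidine to glutamate)
  substrate: histidine
  products:
  - ammonia
  evidence_only: no
  sub_pathways:
  - sub_id: hut
    category: I
    proximity_set:
    - hutH
    - hutU
    - hutI
    - hutG
    - ftcD
    components:
    - component_id: hutH
      ec_number: 4.3.1.3
      domain_ids:
      - PDOM_4_3_1_3
      role: proximal-core
    - component_id: hutU
      ec_number: 4.2.1.49
      domain_ids:
      - PDOM_4_2_1_49
      role: proximal-core
    - component_id: hutI
      ec_number: 3.5.2.7
      domain_ids:
      - PDOM_3_5_2_7
      role: proximal-core
    - component_id: hutG
      ec_number: 3.5.3.8
      domain_ids:
      - PDOM_3_5_3_8
      role: proximal-core
      alternative_group: formiminoglutamate_step
    - component_id: ftcD
      ec_number: 2.1.2.5
      domain_ids:
      - PDOM_2_1_2_5
      role: proximal-core
      alternative_group: formiminoglutamate_step
- pathway_id: thf_production
  name: THF production (histidine to tetrahydrofolate)
  substrate: histidine
  products:
  - ammonia
  evidence_only: no
  sub_pathways:
  - sub_id: hut_thf
    category: I
    proximity_set:
    - hutH
    - hutU
    - hutI
    - ftcD
    - ftcD_cyclodeaminase
    components:
    - component_id: hutH
      ec_number: 4.3.1.3
      domain_ids:
      - PDOM_4_3_1_3
      role: proximal-core
    - component_id: hutU
      ec_number: 4.2.1.49
      domain_ids:
      - PDOM_4_2_1_49
      role: proximal-core
    - component_id: hutI
      ec_number: 3.5.2.7
      domain_ids:
      - PDOM_3_5_2_7
      role: proximal-core
    - component_id: ftcD
      ec_number: 2.1.2.5
      domain_ids:
      - PDOM_2_1_2_5
      role: proximal-core
    - component_id: ftcD_cyclodeaminase
      ec_number: 4.3.1.4
      domain_ids:
      - PDOM_4_3_1_4
      role: proximal-core
- pathway_id: glutamate_degradation
  name: Glutamate degradation (glutamate to acetate + pyruvate)
  substrate: glutamate
  products:
  - ammonia
  evidence_only: no
  sub_pathways:
  - sub_id: methylaspartate
    category: II
    proximity_set:
    - glmE
    - mal
    components:
    - component_id: glmE
      ec_number: 5.4.99.1
      domain_ids:
      - PDOM_5_4_99_1
      role: proximal-core
    - component_id: mal
      ec_number: 4.3.1.2
      domain_ids:
      - PDOM_4_3_1_2
      role: proximal-core
    - component_id: mesaconase
      ec_number: 4.2.1.34
      domain_ids:
      - PDOM_4_2_1_34
      role: distal
    - component_id: citramalate_lyase
      ec_number: 4.1.3.22
      domain_ids:
      - PDOM_4_1_3_22
      role: distal
- pathway_id: putrescine_production
  name: Putrescine production (arginine to putrescine)
  substrate: arginine
  products:
  - putrescine
  evidence_only: no
  sub_pathways:
  - sub_id: odc
    category: I
    proximity_set:
    - arginase
    - odc
    components:
    - component_id: arginase
      ec_number: 3.5.3.1
      domain_ids:
      - Arginase
      role: proximal-core
    - component_id: odc
      ec_number: 4.1.1.17
      domain_ids:
      - OKR_DC_1
      role: proximal-core
  - sub_id: agmatinase
    category: I
    proximity_set:
    - adc
    - speB_agmatinase
    components:
    - component_id: adc
      ec_number: 4.1.1.19
      domain_ids:
      - PDOM_4_1_1_19
      role: proximal-core
    - component_id: speB_agmatinase
      ec_number: 3.5.3.11
      domain_ids:
      - PDOM_3_5_3_11
      role: proximal-core
  - sub_id: agu
    category: II
    proximity_set:
    - aguA
    - aguB
    components:
    - component_id: aguA
      ec_number: 3.5.3.12
      domain_ids:
      - PDOM_3_5_3_12
      role: proximal-core
    - component_id: aguB
      ec_number: 3.5.1.53
      domain_ids:
      - PDOM_3_5_1_53
      role: proximal-core
    - component_id: adc
      ec_number: 4.1.1.19
      domain_ids:
      - PDOM_4_1_1_19
      role: distal
- pathway_id: spermidine_production
  name: Spermidine/spermine production (methionine route)
  substrate: methionine
  products:
  - spermidine
  - spermine
  evidence_only: no
  sub_pathways:
  - sub_id: spe
    category: II
    proximity_set:
    - speD
    - speE
    components:
    - component_id: speD
      ec_number: 4.1.1.50
      domain_ids:
      - PDOM_4_1_1_50
      role: proximal-core
    - component_id: speE
      ec_number: 2.5.1.16
      domain_ids:
      - PDOM_2_5_1_16
      role: proximal-core
    - component_id: metK
      ec_number: 2.5.1.6
      domain_ids:
      - PDOM_2_5_1_6
      role: distal
- pathway_id: cresol_production
  name: Cresol production (tyrosine via p-HPA, hpdBCA operon)
  substrate: tyrosine
  products:
  - cresol
  evidence_only: yes
  sub_pathways:
  - sub_id: hpd
    category: II
    proximity_set:
    - hpdB
    - hpdC
    - hpdA
    components:
    - component_id: hpdB
      ec_number: 4.1.1.83
      domain_ids:
      - PDOM_4_1_1_83
      role: proximal-core
    - component_id: hpdC
      ec_number: ''
      domain_ids: []
      role: proximal-core
      evidence_only: yes
    - component_id: hpdA
      ec_number: ''
      domain_ids:
      - PDOM_hpdA
      role: proximal-core
- pathway_id: indole_production
  name: Indole production (tryptophanase)
  substrate: tryptophan
  products:
  - indole
  evidence_only: no
  sub_pathways:
  - sub_id: tna
    category: III
    proximity_set: []
    components:
    - component_id: tnaA
      ec_number: 4.1.99.1
      domain_ids:
      - PDOM_4_1_99_1
      role: standalone
- pathway_id: phenol_production
  name: Phenol production (tyrosine phenol-lyase)
  substrate: tyrosine
  products:
  - phenol
  evidence_only: no
  sub_pathways:
  - sub_id: tpl
    category: III
    proximity_set: []
    components:
    - component_id: tpl
      ec_number: 4.1.99.2
      domain_ids:
      - PDOM_4_1_99_2
      role: standalone
- pathway_id: cadaverine_production
  name: Cadaverine production (lysine decarboxylase)
  substrate: lysine
  products:
  - cadaverine
  evidence_only: no
  sub_pathways:
  - sub_id: ldc
    category: III
    proximity_set: []
    components:
    - component_id: ldc
      ec_number: 4.1.1.18
      domain_ids:
      - PDOM_4_1_1_18
      role: standalone
- pathway_id: h2s_production
  name: Hydrogen sulfide production (cysteine, five enzymes)
  substrate: cysteine
  products:
  - H2S
  evidence_only: no
  sub_pathways:
  - sub_id: cys
    category: III
    proximity_set: []
    components:
    - component_id: cystathionine_beta_synthase
      ec_number: 4.2.1.22
      domain_ids:
      - PDOM_4_2_1_22
      role: standalone
      alternative_group: h2s_any
    - component_id: cystathionine_gamma_lyase
      ec_number: 4.4.1.1
      domain_ids:
      - PDOM_4_4_1_1
      role: standalone
      alternative_group: h2s_any
    - component_id: mercaptopyruvate_sulfurtransferase
      ec_number: 2.8.1.2
      domain_ids:
      - PDOM_2_8_1_2
      role: standalone
      alternative_group: h2s_any
    - component_id: cysteine_synthase
      ec_number: 2.5.1.47
      domain_ids:
      - PDOM_2_5_1_47
      role: standalone
      alternative_group: h2s_any
    - component_id: cysteine_aminotransferase
      ec_number: 2.6.1.75
      domain_ids:
      - PDOM_2_6_1_75
      role: standalone
      alternative_group: h2s_any
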