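rules:
- name: MAN1_trim
  enzyme: MAN1
  action: remove
  target:
    sugar: Man
    linkage: '2.1'
    leaf: yes
  guards:
    antennae_max: 0
  scale_factor_id: MAN1_man6
- name: EndoMan_deglc
  enzyme: EndoMan
  action: remove_subtree
  target:
    glc_cap_unit: yes
  guards:
    antennae_max: 0
- name: MGAT1_first_antenna
  enzyme: MGAT1
  action: add
  sugar: GlcNAc
  linkage: '2.1'
  target:
    sugar: Man
    linkage: '3.1'
    leaf: yes
    parent_is_core: yes
  guards:
    man_eq: 5
    glc_eq: 0
    antennae_max: 0
- name: MAN2_trim
  enzyme: MAN2
  action: remove
  target:
    sugar: Man
    linkage:
    - '3.1'
    - '6.1'
    leaf: yes
    parent_arm6: yes
  guards:
    antennae_min: 1
- name: MGAT2_second_antenna
  enzyme: MGAT2
  action: add
  sugar: GlcNAc
  linkage: '2.1'
  target:
    sugar: Man
    linkage: '6.1'
    leaf: yes
    parent_is_core: yes
  guards:
    man_eq: 3
    antennae_min: 1
- name: MGAT4_third_antenna
  enzyme: MGAT4
  action: add
  sugar: GlcNAc
  linkage: '4.1'
  target:
    sugar: Man
    linkage: '3.1'
    parent_is_core: yes
    has_bare_gn_child: yes
    lacks_child_at: '4.1'
  guards:
    man_eq: 3
    antennae_min: 2
- name: MGAT5_fourth_antenna
  enzyme: MGAT5
  action: add
  sugar: GlcNAc
  linkage: '6.1'
  target:
    sugar: Man
    linkage: '6.1'
    parent_is_core: yes
    has_bare_gn_child: yes
    lacks_child_at: '6.1'
  guards:
    man_eq: 3
    antennae_min: 2
- name: GalT_antenna
  enzyme: GalT
  action: add
  sugar: Gal
  linkage: '4.1'
  target:
    sugar: GlcNAc
    parent_sugar: Man
    lacks_child_sugar: Gal
  guards:
    antennae_min: 1
  scale_factor_id: GalT_branched
- name: SiaT_cap
  enzyme: SiaT
  action: add
  sugar: NeuAc
  linkage: '6.2'
  target:
    sugar: Gal
    lacks_child_sugar: NeuAc
  guards:
    antennae_min: 1
  scale_factor_id: SiaT_arm6
- name: FUT8_core
  enzyme: FUT8
  action: add
  sugar: Fuc
  linkage: '6.1'
  target:
    is_root: yes
    lacks_child_sugar: Fuc
  guards:
    antennae_min: 1
  scale_factor_id: FUT8_man5
- name: FUT8_core_man5
  enzyme: FUT8
  action: add
  sugar: Fuc
  linkage: '6.1'
  target:
    is_root: yes
    lacks_child_sugar: Fuc
  guards:
    man_eq: 5
    antennae_max: 0
    glc_eq: 0
  scale_factor_id: FUT8_man5
- name: antFUT_antenna
  enzyme: antFUT
  action: add
  sugar: Fuc
  linkage: '3.1'
  target:
    sugar: GlcNAc
    parent_sugar: Man
    lacks_child_sugar: Fuc
    no_sia_in_subtree: yes
  guards:
    man_eq: 3
- name: OM_quench
  enzyme: OMquench
  action: quench
  guards:
    class_in: oligomannose
scale_factors:
- id: MAN1_man6
  enzyme: MAN1
  multiplier: 0.2
  man_eq: 6
- id: FUT8_man5
  enzyme: FUT8
  multiplier: 0.1
  man_eq: 5
- id: GalT_branched
  enzyme: GalT
  multiplier: 0.5
  antennae_min: 3
- id: SiaT_arm6
  enzyme: SiaT
  multiplier: 0.5
  arm: '6.1'

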