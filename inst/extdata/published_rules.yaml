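# Published CPD discriminant registry (Beckman Coulter DxH 800 VCS
# parameters), as derived on the original 1348-sample retrospective
# cohort (1103 non-neoplastic, 245 neoplastic).
#
# Orientations of the stage-1 rules follow the published cutoff tables
# (neoplastic side printed explicitly). The published sources give no
# direction for the reactive discriminant or the subtype rules; the
# orientations below are provisional configuration defaults chosen on
# haematological plausibility and can be relearned from a labelled
# cohort with the calibration functions.
version: 1
provenance: published DxH 800 retrospective derivation cohort
provisional_orientations:
  - reactive_mn_al2_ne
  - aml_sd_mals_ne
  - aml_sd_umals_ne
  - apl_mn_v_ne
  - apl_sd_v_mo
  - all_mn_mals_ne
  - all_mn_lmals_ne
  - cll_sd_c_mo
rules:
  - name: neoplastic_composite
    numerator: [SD-V-NE, MN-UMALS-LY, SD-AL2-MO]
    denominator: [MN-C-NE]
    cutoff: 106.44
    orientation: high_is_positive
    positive_label: neoplastic
    negative_label: non-neoplastic
  - name: sd_v_ne
    numerator: [SD-V-NE]
    cutoff: 18.95
    orientation: high_is_positive
    positive_label: neoplastic
    negative_label: non-neoplastic
  - name: mn_c_ne
    numerator: [MN-C-NE]
    cutoff: 148.50
    orientation: low_is_positive
    positive_label: neoplastic
    negative_label: non-neoplastic
  - name: mn_umals_ly
    numerator: [MN-UMALS-LY]
    cutoff: 59.50
    orientation: high_is_positive
    positive_label: neoplastic
    negative_label: non-neoplastic
  - name: sd_al2_mo
    numerator: [SD-AL2-MO]
    cutoff: 16.20
    orientation: high_is_positive
    positive_label: neoplastic
    negative_label: non-neoplastic
  - name: reactive_mn_al2_ne
    numerator: [MN-AL2-NE]
    cutoff: 147.5
    orientation: low_is_positive
    positive_label: neoplastic
    negative_label: reactive
  - name: aml_sd_mals_ne
    numerator: [SD-MALS-NE]
    cutoff: 15.81
    orientation: high_is_positive
    positive_label: AML
    negative_label: other
    subtype: AML
  - name: aml_sd_umals_ne
    numerator: [SD-UMALS-NE]
    cutoff: 17.70
    orientation: high_is_positive
    positive_label: AML
    negative_label: other
    subtype: AML
  - name: apl_mn_v_ne
    numerator: [MN-V-NE]
    cutoff: 159.50
    orientation: high_is_positive
    positive_label: APL
    negative_label: other
    subtype: APL
  - name: apl_sd_v_mo
    numerator: [SD-V-MO]
    cutoff: 33.68
    orientation: high_is_positive
    positive_label: APL
    negative_label: other
    subtype: APL
  - name: all_mn_mals_ne
    numerator: [MN-MALS-NE]
    cutoff: 129.50
    orientation: low_is_positive
    positive_label: ALL
    negative_label: other
    subtype: ALL
  - name: all_mn_lmals_ne
    numerator: [MN-LMALS-NE]
    cutoff: 122.50
    orientation: low_is_positive
    positive_label: ALL
    negative_label: other
    subtype: ALL
  - name: cll_sd_c_mo
    numerator: [SD-C-MO]
    cutoff: 11.10
    orientation: low_is_positive
    positive_label: CLL
    negative_label: other
    subtype: CLL
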