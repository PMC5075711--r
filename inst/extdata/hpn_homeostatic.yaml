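schema_version: 1
type: hpn
name: era-hpn
variant: homeostatic
places:
- name: Ligand
  kind: continuous
  marking: 5.0
- name: Receptor
  kind: continuous
  marking: 5.0
- name: Complex
  kind: continuous
  marking: 0.0
- name: ER-alpha
  kind: continuous
  marking: 0.0
- name: BRCA1
  kind: continuous
  marking: 0.0
- name: p53
  kind: continuous
  marking: 0.0
- name: Mdm2
  kind: continuous
  marking: 0.0
transitions:
- name: bind
  rate: 1.0
- name: lig_clear
  rate: 1.0
- name: er_prod
  rate: 1.0
- name: er_deg
  rate: 1.0
- name: p53_prod
  rate: 1.0
- name: p53_deg
  rate: 1.0
- name: brca_prod
  rate: 1.0
- name: mdm2_prod
  rate: 1.0
arcs:
- from: Ligand
  to: bind
  kind: normal
  weight: 1.0
- from: Receptor
  to: bind
  kind: normal
  weight: 1.0
- from: Complex
  to: bind
  kind: inhibitory
  weight: 1.0
- from: bind
  to: Complex
  kind: normal
  weight: 1.0
- from: Ligand
  to: lig_clear
  kind: normal
  weight: 1.0
- from: Complex
  to: er_prod
  kind: test
  weight: 1.0
- from: Mdm2
  to: er_prod
  kind: inhibitory
  weight: 1.0
- from: er_prod
  to: ER-alpha
  kind: normal
  weight: 1.0
- from: ER-alpha
  to: er_deg
  kind: normal
  weight: 1.0
- from: p53_prod
  to: p53
  kind: normal
  weight: 1.0
- from: p53
  to: p53_deg
  kind: normal
  weight: 1.0
- from: Mdm2
  to: p53_deg
  kind: test
  weight: 1.0
- from: p53
  to: brca_prod
  kind: test
  weight: 1.0
- from: BRCA1
  to: brca_prod
  kind: inhibitory
  weight: 1.0
- from: brca_prod
  to: BRCA1
  kind: normal
  weight: 1.0
- from: p53
  to: mdm2_prod
  kind: test
  weight: 1.0
- from: Mdm2
  to: mdm2_prod
  kind: inhibitory
  weight: 2.0
- from: mdm2_prod
  to: Mdm2
  kind: normal
  weight: 1.0
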