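# Parameter manifest binding the model tables.
#
# All tables are package-authored defaults for the ten-group colonic community
# model; half_saturation_g_per_L applies to every group and substrate, with
# per-resource conversion to mM where the resource is tracked molar.
schema_version: 1
half_saturation_g_per_L: 0.001
tables:
  resources: resources.tsv
  growth: mfg_growth.tsv
  ph_corners: mfg_ph_corners.tsv
  stoichiometry: mfg_stoichiometry.tsv
  lactate_ki: mfg_ki.tsv
mfg_descriptions:
  M1: "Propionate producers (Bacteroidetes)"
  M2: "Starch-degrading acetate producers (Ruminococcus bromii)"
  M3: "Acetate producers, nonacetogenic (Lachnospiraceae/Ruminococcaceae)"
  M4: "Lactate producers (Actinobacteria, lactobacilli and relatives)"
  M5: "Butyrate producers 1 (Roseburia, Eubacterium rectale)"
  M6: "Butyrate producers 2 (Faecalibacterium, Subdoligranulum)"
  M7: "Lactate utilizers producing propionate (Negativicutes, Coprococcus catus)"
  M8: "Lactate utilizers producing butyrate (Anaerostipes, Anaerobutyricum)"
  M9: "Acetogens (Blautia)"
  M10: "Methanogens (methanogenic archaea)"
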