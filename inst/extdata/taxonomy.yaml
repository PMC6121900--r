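# Ordered rule table for PTM class normalization and residue-chemistry grouping.
# First match wins everywhere; extend by prepending rules.
#
# canonical: known class spellings. Matching is case-insensitive after
#   cross-link partner qualifiers ("(interchain with ...)") are stripped;
#   chemistry qualifiers like "(Lys-Gly)", "(GlcNAc)" are part of the name.
#   target: the single modified residue (one-letter code), or null when the
#   class has no unique target (e.g. O-linked glycans attach to Ser or Thr).
canonical:
  - {name: "Phosphoserine",                                    target: "S"}
  - {name: "Phosphothreonine",                                 target: "T"}
  - {name: "Phosphotyrosine",                                  target: "Y"}
  - {name: "Phosphohistidine",                                 target: "H"}
  - {name: "N6-acetyllysine",                                  target: "K"}
  - {name: "N6-methyllysine",                                  target: "K"}
  - {name: "N6,N6-dimethyllysine",                             target: "K"}
  - {name: "N6,N6,N6-trimethyllysine",                         target: "K"}
  - {name: "N6-succinyllysine",                                target: "K"}
  - {name: "N6-malonyllysine",                                 target: "K"}
  - {name: "N6-crotonyllysine",                                target: "K"}
  - {name: "N6-biotinyllysine",                                target: "K"}
  - {name: "Glycyl lysine isopeptide (Lys-Gly)",               target: "K"}
  - {name: "Glycyl lysine isopeptide (Gly-Lys)",               target: "K"}
  - {name: "S-cysteinyl 3-(oxidosulfanyl)alanine (Cys-Cys)",   target: "C"}
  - {name: "S-nitrosocysteine",                                target: "C"}
  - {name: "S-palmitoyl cysteine",                             target: "C"}
  - {name: "S-glutathionyl cysteine",                          target: "C"}
  - {name: "S-farnesyl cysteine",                              target: "C"}
  - {name: "N-acetylmethionine",                               target: "M"}
  - {name: "N-acetylthreonine",                                target: "T"}
  - {name: "N-acetylserine",                                   target: "S"}
  - {name: "N-acetylalanine",                                  target: "A"}
  - {name: "N-acetylvaline",                                   target: "V"}
  - {name: "N-linked (GlcNAc)",                                target: "N"}
  - {name: "N-myristoyl glycine",                              target: "G"}
  - {name: "Omega-N-methylarginine",                           target: "R"}
  - {name: "O-linked (GalNAc)",                                target: null}
  - {name: "O-linked (GlcNAc)",                                target: null}
  - {name: "O-linked (Fuc)",                                   target: null}
  - {name: "O-linked (Man)",                                   target: null}
  - {name: "C-linked (Man)",                                   target: "W"}
  - {name: "4-hydroxyproline",                                 target: "P"}
  - {name: "3-hydroxyproline",                                 target: "P"}
  - {name: "5-hydroxylysine",                                  target: "K"}
  - {name: "Pyrrolidone carboxylic acid",                      target: "Q"}
  - {name: "Citrulline",                                       target: "R"}

# group rules: ordered regular expressions over the canonical class name
# (case-insensitive). Groups follow the residue-chemistry breakdown used for
# the headline percentages: phosphorylation; modifications of the lysine
# epsilon (N6) amino group; Gly-Lys isopeptide coupling (ubiquitin signature,
# kept separate from LYSINE_N6); sulfur-attached; other nitrogen-attached;
# everything else.
group_rules:
  - {pattern: "^Phospho",                    group: "PHOSPHORYLATION"}
  - {pattern: "^N6[-,]",                     group: "LYSINE_N6"}
  - {pattern: "^Glycyl lysine isopeptide",   group: "GLY_LYS_ISOPEPTIDE"}
  - {pattern: "^S-",                         group: "SULFUR"}
  - {pattern: "^N-",                         group: "OTHER_NITROGEN"}
  - {pattern: "^Omega-N-",                   group: "OTHER_NITROGEN"}

# Whether Gly-Lys isopeptide coupling is folded into LYSINE_N6 for the
# protein-level lysine-N6 statistic; class percentages always keep the two
# groups separate.
isopeptide_counts_as_n6: false
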