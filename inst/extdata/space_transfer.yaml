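# Transfer-learning space: the full seven-parameter layout with expanded
# continuous ranges, shared by the later substrate campaigns.  The eighth
# "sugar" task categorical is added programmatically with augment_with_task()
# so its level set always matches the task library in use.
name: transfer
metadata:
  reaction: "regioselective benzoylation, substrate-transfer campaigns"
  constants:
    reaction_time_h: 1
    temperature: ambient
parameters:
  - name: eq_bz
    kind: continuous
    lower: 0.5
    upper: 10.0
  - name: eq_base
    kind: continuous
    lower: 1.0
    upper: 30.0
  - name: conc
    kind: continuous
    lower: 0.02
    upper: 0.2
  - name: bz_reagent
    kind: ordinal
    levels: [1, 2]
    labels: [BzCl, Bz2O]
  - name: base
    kind: ordinal
    levels: [1, 2, 3, 4, 5, 6, 7, 8, 9]
    labels: [Et3N, DIPEA, DBU, DMAP, Pyridine, 2-Picoline, "2,6-Lutidine",
             Collidine, Aniline]
  - name: t1
    kind: ordinal
    levels: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17,
             18, 19, 20]
  - name: solvent
    kind: categorical
    levels: [MeCN, THF, Dioxane, DMF, MeCN/THF, MeCN/Dioxane, MeCN/DMF,
             THF/Dioxane, THF/DMF, Dioxane/DMF]
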