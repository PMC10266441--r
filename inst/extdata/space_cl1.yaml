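# Initial closed-loop space: regioselective 6-O-benzoylation of a
# beta-glucoside.  Seven searched parameters; reaction time (1 h) and ambient
# temperature are constants and live in metadata.  Continuous ranges are this
# package's documented assumptions: only the base maximum (16.7 eq) is pinned
# by the published campaign, the rest bracket the optima reported there with
# headroom on both sides.
name: cl1
metadata:
  reaction: "6-O-monobenzoylation of beta-glucoside"
  constants:
    reaction_time_h: 1
    temperature: ambient
  note: "stock solutions add fixed DMF (sugar) and MeCN (Bz2O) to every run"
parameters:
  - name: eq_bz
    kind: continuous
    lower: 0.5
    upper: 6.0
  - name: eq_base
    kind: continuous
    lower: 1.0
    upper: 16.7
  - name: conc
    kind: continuous
    lower: 0.025
    upper: 0.175
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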