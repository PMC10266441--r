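# Second closed-loop space: reagent and base frozen to the winners of the
# first loop (Bz2O, Et3N), the base ceiling raised to 30 eq because the first
# optimum sat on the old ceiling, and the 10-level solvent categorical
# replaced by a continuous MeCN:THF composition (solvent_ratio = volume
# fraction THF; 0 = pure MeCN, 1 = pure THF).  The dibenzoylation loop (CL3)
# reuses this same space with the objective switched to the di product.
name: cl2
metadata:
  reaction: "6-O-monobenzoylation of beta-glucoside, refined solvent system"
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
    lower: 0.025
    upper: 0.175
  - name: bz_reagent
    kind: ordinal
    levels: [1, 2]
    labels: [BzCl, Bz2O]
    fixed: 2
  - name: base
    kind: ordinal
    levels: [1, 2, 3, 4, 5, 6, 7, 8, 9]
    labels: [Et3N, DIPEA, DBU, DMAP, Pyridine, 2-Picoline, "2,6-Lutidine",
             Collidine, Aniline]
    fixed: 1
  - name: t1
    kind: ordinal
    levels: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17,
             18, 19, 20]
  - name: solvent_ratio
    kind: continuous
    lower: 0.0
    upper: 1.0
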