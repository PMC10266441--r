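# Reconstructed physicochemical descriptor table for the nine candidate
# bases.  Values were re-collected from public reference sources (solvent
# property tables, PubChem, aqueous pKa compilations); they are an
# approximate reconstruction, not the original campaign's table, and carry
# ordinary literature uncertainty (densities/RIs of solids are estimates).
# Units: mw g/mol, density g/mL, ri (20 C), mp/bp C, logp, dipole D,
# tpsa A^2, pkah (conjugate acid, water).
item,mw,density,ri,mp,bp,logp,dipole,tpsa,pkah
Et3N,101.19,0.726,1.401,-114.7,89.0,1.45,0.66,3.2,10.75
DIPEA,129.25,0.742,1.414,-46.0,127.0,2.41,0.78,3.2,10.98
DBU,152.24,1.018,1.522,-70.0,261.0,1.23,3.00,15.6,12.00
DMAP,122.17,1.080,1.550,112.0,262.0,1.20,4.30,16.1,9.70
Pyridine,79.10,0.982,1.509,-41.6,115.2,0.65,2.22,12.9,5.25
2-Picoline,93.13,0.943,1.498,-66.7,129.4,1.11,1.85,12.9,5.97
"2,6-Lutidine",107.15,0.920,1.497,-6.1,144.0,1.68,1.66,12.9,6.65
Collidine,121.18,0.917,1.498,-44.5,170.4,1.98,2.05,12.9,7.43
Aniline,93.13,1.022,1.586,-6.0,184.1,0.90,1.53,26.0,4.60
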