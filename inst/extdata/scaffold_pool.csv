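name,pool,smiles
anthracene,interferent,c1ccc2cc3ccccc3cc2c1
phenanthrene,interferent,c1ccc2c(c1)ccc1ccccc21
pyrene,interferent,c1cc2ccc3cccc4ccc(c1)c2c34
tetracene,interferent,c1ccc2cc3cc4ccccc4cc3cc2c1
acridine,interferent,c1ccc2nc3ccccc3cc2c1
phenazine,interferent,c1ccc2nc3ccccc3nc2c1
phenylxanthene,interferent,c1ccc(cc1)C1c2ccccc2Oc2ccccc21
naphthyl_azobenzene,interferent,c1ccc(cc1)N=Nc1ccc2ccccc2c1
aminoazo_biphenyl,interferent,Nc1ccc(cc1)N=Nc1ccc(cc1)-c1ccccc1
p_terphenyl,interferent,c1ccc(cc1)-c1ccc(cc1)-c1ccccc1
triphenylmethane,interferent,C(c1ccccc1)(c1ccccc1)c1ccccc1
diphenylanthracene,interferent,c1ccc(cc1)-c1c2ccccc2c(-c2ccccc2)c2ccccc12
anthracenediol,interferent,Oc1ccc2cc3cc(O)ccc3cc2c1
naphthyl_phenyl_ketone,interferent,c1ccc(cc1)C(=O)c1ccc2ccccc2c1
naphthyl_phenyl_ether,interferent,c1ccc(cc1)Oc1ccc2ccccc2c1
naphthyl_phenyl_sulfone,interferent,c1ccc(cc1)S(=O)(=O)c1ccc2ccccc2c1
bis_naphthyl_azo,interferent,c1ccc2cc(N=Nc3ccc4ccccc4c3)ccc2c1
phenylfluorene,interferent,c1ccc(cc1)C1c2ccccc2-c2ccccc21
trityl_diphenol,interferent,Oc1ccc(cc1)C(c1ccc(O)cc1)c1ccccc1
distyrylbenzene,interferent,c1ccc(cc1)C=Cc1ccc(cc1)C=Cc1ccccc1
octane,decoy,CCCCCCCC
dodecane,decoy,CCCCCCCCCCCC
isooctane,decoy,CC(C)CC(C)(C)C
cyclohexane,decoy,C1CCCCC1
bicyclohexyl,decoy,C1CCC(CC1)C1CCCCC1
glycerol,decoy,OCC(O)CO
diethyl_adipate,decoy,CCOC(=O)CCCC(=O)OCC
butyl_hexanoate,decoy,CCCCOC(=O)CCCCC
methyl_thf,decoy,CC1CCOC1
hexanediol,decoy,OCCCCCCO
pentanoic_acid,decoy,CCCCC(=O)O
decalin,decoy,C1CCC2CCCCC2C1
menthane,decoy,CC1CCC(C(C)C)CC1
hexanediamine,decoy,NCCCCCCN
dibutyl_sulfide,decoy,CCCCSCCCC
sebacic_acid,decoy,OC(=O)CCCCCCCCC(=O)O
diisopropyl_ether,decoy,CC(C)OC(C)C
triethylpentane,decoy,CCC(CC)(CC)CC
ethylene_glycol_dibutyrate,decoy,CCCC(=O)OCCOC(=O)CCC
cyclopentanol,decoy,OC1CCCC1
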