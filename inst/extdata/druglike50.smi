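CC(=O)Oc1ccccc1C(=O)O aspirin
CC(=O)Nc1ccc(O)cc1 paracetamol
CC(C)Cc1ccc(C(C)C(=O)O)cc1 ibuprofen
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CN1CCCC1c1cccnc1 nicotine
CCOC(=O)c1ccc(N)cc1 benzocaine
CCN(CC)CCOC(=O)c1ccc(N)cc1 procaine
CCN(CC)CC(=O)Nc1c(C)cccc1C lidocaine
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1 atenolol
CC(C)NCC(O)COc1cccc2ccccc12 propranolol
COCCc1ccc(OCC(O)CNC(C)C)cc1 metoprolol
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol
CN(C)CCOC(c1ccccc1)c1ccccc1 diphenhydramine
CN(C)CCC(c1ccc(Cl)cc1)c1ccccn1 chlorpheniramine
COc1ccc2cc(C(C)C(=O)O)ccc2c1 naproxen
CC(C(=O)O)c1cccc(C(=O)c2ccccc2)c1 ketoprofen
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl diclofenac
Cc1cccc(C)c1Nc1ccccc1C(=O)O mefenamic_acid
NC(=O)c1ccccc1 benzamide
Nc1ccc(S(N)(=O)=O)cc1 sulfanilamide
Nc1ccc(cc1)S(=O)(=O)Nc1cc(C)on1 sulfamethoxazole
COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC trimethoprim
Cc1ncc([N+](=O)[O-])n1CCO metronidazole
OC(Cn1cncn1)(Cn1cncn1)c1ccc(F)cc1F fluconazole
CC(=O)NCCc1c[nH]c2ccc(OC)cc12 melatonin
NCCc1c[nH]c2ccc(O)cc12 serotonin
NC(Cc1c[nH]c2ccccc12)C(=O)O tryptophan
O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1 phenytoin
NC(=O)N1c2ccccc2C=Cc2ccccc21 carbamazepine
CN(C)CCC=C1c2ccccc2CCc2ccccc21 amitriptyline
CN(C)CCCN1c2ccccc2CCc2ccccc21 imipramine
OC1(c2ccc(Cl)cc2)CCN(CCCC(=O)c2ccc(F)cc2)CC1 haloperidol
CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21 diazepam
COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1 omeprazole
OC(=O)COCCN1CCN(C(c2ccccc2)c2ccc(Cl)cc2)CC1 cetirizine
CC(=O)CC(c1ccccc1)C1=C(O)c2ccccc2OC1=O warfarin
Cc1ccc(cc1)c1cc(nn1c1ccc(cc1)S(N)(=O)=O)C(F)(F)F celecoxib
NCC1(CC(=O)O)CCCCC1 gabapentin
CC(C)CC(CN)CC(=O)O pregabalin
CN(C)CC(c1ccc(OC)cc1)C1(O)CCCCC1 venlafaxine
CC(NC(C)(C)C)C(=O)c1cccc(Cl)c1 bupropion
CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1 fluoxetine
CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21 sertraline
CN(C)CCCC1(c2ccc(F)cc2)OCc2cc(C#N)ccc21 citalopram
CCOC(=O)N1CCC(=C2c3ccc(Cl)cc3CCc3cccnc32)CC1 loratadine
CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1 tolbutamide
NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl furosemide
COc1ccc(Cc2nccc3cc(OC)c(OC)cc23)cc1OC papaverine
Nc1ccc(cc1)S(=O)(=O)c1ccc(N)cc1 dapsone
CCCCC1C(=O)N(c2ccccc2)N(c2ccccc2)C1=O phenylbutazone
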