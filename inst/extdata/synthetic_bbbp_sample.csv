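"num","name","p_np","smiles"
"M00010","synthetic-00010",0,"OCC1CCCC1CCN1CCCCC1"
"M00039","synthetic-00039",1,"CNC(=O)CC1CC(CCC1CCN1CCC1)C(F)(F)F"
"M00026","synthetic-00026",0,"N#CC1(COCC1CCN1CCCCC1)C(F)(F)F"
"M00014","synthetic-00014",1,"CC(CC1CCCC1)CCCN1CCC1"
"tri2","synthetic-00035",1,"N#CC1CCCC1CCN1CCC1"
"M00023","synthetic-00023",1,"N#Cc1ccc(c2c1cccc2)CCN1CCC1"
"M00022","synthetic-00022",1,"O=CCC1CCCC1CCN1CCC1"
"M00006","synthetic-00006",1,"CC(C1CCOC1CCN1CCC1)O"
"M00004","synthetic-00004",0,"ClCc1c(CCN2CCCCC2)cccc1C(F)(F)F"
"dup2","synthetic-00022",1,"O=CCC1CCCC1CCN1CCC1"
"M00035","synthetic-00035",1,"N#CC1CCCC1CCN1CCC1"
"M00007","synthetic-00007",1,"CC(Cc1ccccc1CCN1CCC1)C"
"M00038","synthetic-00038",1,"O=C(CC1CCCC1C(O)C)NCCCN1CCC1"
"M00018","synthetic-00018",1,"COC(c1cccc(c1)CCN1CCC1)CN(C)C"
"M00012","synthetic-00012",0,"OC(c1ccccc1)Cc1cnccc1CCN1CCCCC1"
"M00008","synthetic-00008",0,"ClCc1ccc(cc1)CCN1CCCCC1"
"M00036","synthetic-00036",1,"OCc1cc(CCN2CCC2)cc2c1cccc2"
"badn1","quaternary-1",1,"CC[N](C)(C)CC"
"M00002","synthetic-00002",1,"OCC(c1ccc2c(c1)ccc(c2)CO)CCN1CCC1"
"M00019","synthetic-00019",1,"CCC1(CCCCC1)CCN1CCC1"
"dup1","synthetic-00034",1,"CC(C1C(CCN2CCC2)COC1C(F)(F)F)O"
"M00029","synthetic-00029",1,"CNC(=O)CCCc1cccc(c1)CCN1CCC1"
"M00020","synthetic-00020",1,"c1ccc(cc1)CCCCN1CCC1"
"M00016","synthetic-00016",1,"CC(=O)C1COC(C1)CCN1CCC1"
"M00021","synthetic-00021",1,"CNC(=O)C(C1CCC(C1)CCN1CCC1)CC(C)C"
"M00037","synthetic-00037",0,"ClCC1CCCCC1(CCN1CCCCC1)C(O)C"
"M00032","synthetic-00032",0,"CNC(=O)C(c1cc(CC)cc2c1cccc2)CCN1CCCCC1"
"M00011","synthetic-00011",1,"CN(CC1CCOC1CCN1CCC1)C"
"M00027","synthetic-00027",0,"N#CCN(C(C1COCC1)CCN1CCCCC1)C"
"M00031","synthetic-00031",1,"COCc1ccc(c2c1cccc2)CCN1CCC1"
"M00040","synthetic-00040",1,"FC(C1CCCC1CCN1CCC1)(F)F"
"M00013","synthetic-00013",1,"CCC1OCCC1CCN1CCC1"
"conflict1","synthetic-00039",0,"CNC(=O)CC1CC(CCC1CCN1CCC1)C(F)(F)F"
"dup3","synthetic-00036",1,"OCc1cc(CCN2CCC2)cc2c1cccc2"
"M00017","synthetic-00017",1,"CCc1cccnc1CCN1CCC1"
"tri1","synthetic-00035",1,"N#CC1CCCC1CCN1CCC1"
"M00001","synthetic-00001",1,"CNC(=O)CC(C1(CCCCC1)CCN1CCC1)O"
"M00024","synthetic-00024",1,"O=C(C(c1ccccc1)CCN1CCC1)NCC(F)(F)F"
"M00033","synthetic-00033",1,"CN(C(C1COCC1)CCN1CCC1)C"
"M00009","synthetic-00009",0,"COCC1(CCCC(C1)CC)CCN1CCCCC1"
"badn2","quaternary-2",0,"CN(C)(C)Cc1ccccc1"
"M00034","synthetic-00034",1,"CC(C1C(CCN2CCC2)COC1C(F)(F)F)O"
"junk1","unreadable-1",1,"C1CC("
"M00003","synthetic-00003",1,"CC(=O)NCc1ccc(cc1)CCN1CCC1"
"M00005","synthetic-00005",1,"COCC1CC(C(O1)CCN1CCC1)CC=O"
"M00028","synthetic-00028",0,"ClCc1ccc(nc1CCN1CCCCC1)CO"
"M00015","synthetic-00015",1,"N#CC1C(CCN2CCC2)OCC1C#N"
"M00030","synthetic-00030",1,"OCc1ccccc1CCN1CCC1"
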