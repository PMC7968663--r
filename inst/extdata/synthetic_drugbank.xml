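<?xml version="1.0" encoding="UTF-8"?><drugbank><drug><drugbank-id primary="true">SYN00001</drugbank-id><name>Amiloxan</name><groups><group>approved</group></groups><targets><target><id>SYNBE001</id><name>Histamine receptor H1</name><organism>Humans</organism></target><target><id>SYNBE002</id><name>Dopamine receptor D2</name><organism>Humans</organism></target><target><id>SYNBE003</id><name>Serotonin receptor 2A</name><organism>Humans</organism></target></targets><enzymes><enzyme><id>SYNBE900</id><name>Cytochrome P450 2D6</name><organism>Humans</organism></enzyme></enzymes></drug><drug><drugbank-id primary="true">SYN00002</drugbank-id><name>Betaprine</name><groups><group>approved</group><group>withdrawn</group></groups><targets><target><id>SYNBE001</id><name>Histamine receptor H1</name><organism>Humans</organism></target><target><id>SYNBE004</id><name>Copper ion</name><organism>Humans</organism></target></targets></drug><drug><drugbank-id primary="true">SYN00003</drugbank-id><name>Copper ion</name><groups><group>approved</group></groups><targets><target><id>SYNBE005</id><name>Superoxide dismutase</name><organism>Humans</organism></target><target><id>SYNBE006</id><name>Ceruloplasmin</name><organism>Humans</organism></target></targets></drug><drug><drugbank-id primary="true">SYN00004</drugbank-id><name>Gammazole</name><groups><group>investigational</group></groups><targets><target><id>SYNBE002</id><name>Dopamine receptor D2</name><organism>Humans</organism></target></targets></drug><drug><drugbank-id primary="true">SYN00005</drugbank-id><name>Deltamycin</name><groups><group>approved</group></groups><targets><target><id>SYNBE007</id><name>Penicillin-binding protein 2</name><organism>E. coli</organism></target></targets><transporters><transporter><id>SYNBE901</id><name>P-glycoprotein</name><organism>Humans</organism></transporter></transporters></drug><drug><drugbank-id primary="true">SYN00006</drugbank-id><name>Epsilorex</name><groups><group>approved</group></groups><targets><target><id>SYNBE002</id><name>Dopamine receptor D2</name><organism>Humans</organism></target><target><id>SYNBE003</id><name>Serotonin receptor 2A</name><organism>Humans</organism></target></targets></drug><drug><drugbank-id primary="true">SYN00007</drugbank-id><name>Zetadil</name><groups><group>approved</group></groups><targets><target><id>SYNBE008</id><name>Thymidine kinase</name><organism>Human herpesvirus 1</organism></target></targets></drug><drug><drugbank-id primary="true">SYN00008</drugbank-id><name>Etaprost</name><groups><group>approved</group></groups><targets><target><id>SYNBE005</id><name>Superoxide dismutase</name><organism>Humans</organism></target></targets><carriers><carrier><id>SYNBE902</id><name>Serum albumin</name><organism>Humans</organism></carrier></carriers></drug></drugbank>
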