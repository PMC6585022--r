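(Aque:1,(Tadh:0.96,((Hmag:0.5,Nvec:0.5):0.42,(((Cele:0.75,((Agam:0.35,Dmel:0.35):0.15,Amel:0.5):0.25):0.05,(Ctel:0.6,Obim:0.6):0.2):0.08,(((Skow:0.4,Pfla:0.4):0.3,Spur:0.7):0.1,(Bflo:0.76,((Cint:0.3,Csav:0.3):0.42,((Drer:0.45,((Trub:0.15,Tnig:0.15):0.15,(Gacu:0.25,Olat:0.25):0.05):0.15)teleost_crown:0.15,(Xtro:0.48,((Acar:0.38,(Psin:0.3,(Ggal:0.15,Tgut:0.15):0.15):0.08):0.04,(Oana:0.36,(Mdom:0.3,((Lafr:0.2,Dnov:0.2):0.06,((Eeur:0.22,((Mluc:0.14,Pvam:0.14):0.06,((Cfam:0.1,Fcat:0.1):0.06,(Btau:0.12,Ecab:0.12):0.04):0.04):0.02):0.02,((Ocun:0.18,(Rnor:0.12,Mmus:0.12):0.06):0.04,(Cjac:0.16,(Mmul:0.12,(Pabe:0.1,(Ggor:0.08,(Ptro:0.05,Hsap:0.05):0.03):0.02):0.02):0.04):0.06):0.02):0.02):0.04):0.06):0.06):0.06)amphibian_split:0.12)teleost_tetrapod_split:0.12)tunicate_split:0.04)cephalochordate_split:0.04)ambulacrarian_split:0.08)protostome_deuterostome_split:0.04)cnidarian_split:0.04)placozoan_split:0.04)sponge_split;
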