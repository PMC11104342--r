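species,analyte,mean,sd,n
POM,bulk,-0.5,1.4,23
Euphausia superba,bulk,3.5,0.6,75
Themisto gaudichaudii,bulk,4.9,0.8,17
Euphausia frigida,bulk,5.4,0.3,17
Antarctomysis maxima,bulk,5.9,0.4,16
Electrona antarctica,bulk,8.6,0.7,30
Champsocephalus gunnari,bulk,8.5,0.2,284
Euphausia superba,Ala,13.7,2.5,10
Themisto gaudichaudii,Ala,21.1,1.9,3
Euphausia frigida,Ala,17.8,0.8,3
Antarctomysis maxima,Ala,21.0,1.2,3
Electrona antarctica,Ala,23.2,1.4,3
Champsocephalus gunnari,Ala,22.5,0.8,10
Euphausia superba,Asp,11.4,1.5,10
Themisto gaudichaudii,Asp,14.7,0.7,3
Euphausia frigida,Asp,14.4,0.5,3
Antarctomysis maxima,Asp,15.7,0.6,3
Electrona antarctica,Asp,17.9,0.9,3
Champsocephalus gunnari,Asp,16.9,0.5,10
Euphausia superba,Glx,14.9,1.8,10
Themisto gaudichaudii,Glx,19.4,0.4,3
Euphausia frigida,Glx,18.5,0.2,3
Antarctomysis maxima,Glx,21.8,0.6,3
Electrona antarctica,Glx,23.9,1.6,3
Champsocephalus gunnari,Glx,23.1,0.4,10
Euphausia superba,Gly,-3.5,1.1,10
Themisto gaudichaudii,Gly,1.7,0.9,3
Euphausia frigida,Gly,-2.1,0.9,3
Antarctomysis maxima,Gly,-0.4,0.9,3
Electrona antarctica,Gly,-1.1,1.4,3
Champsocephalus gunnari,Gly,-1.7,1.0,10
Euphausia superba,Ile,10.2,1.9,10
Themisto gaudichaudii,Ile,17.9,1.4,3
Euphausia frigida,Ile,9.8,1.6,3
Antarctomysis maxima,Ile,16.6,1.1,3
Electrona antarctica,Ile,22.0,1.5,3
Champsocephalus gunnari,Ile,22.2,1.7,10
Euphausia superba,Leu,10.8,1.1,10
Themisto gaudichaudii,Leu,17.1,1.1,3
Euphausia frigida,Leu,11.9,0.6,3
Antarctomysis maxima,Leu,18.0,0.5,3
Electrona antarctica,Leu,21.0,1.3,3
Champsocephalus gunnari,Leu,21.4,0.6,10
Euphausia superba,Pro,11.4,0.9,10
Themisto gaudichaudii,Pro,14.4,0.6,3
Euphausia frigida,Pro,12.7,1.4,3
Antarctomysis maxima,Pro,15.5,0.7,3
Electrona antarctica,Pro,21.5,1.3,3
Champsocephalus gunnari,Pro,19.8,0.6,10
Euphausia superba,Val,12.9,1.6,10
Themisto gaudichaudii,Val,18.8,0.6,3
Euphausia frigida,Val,14.1,0.2,3
Antarctomysis maxima,Val,18.2,0.9,3
Electrona antarctica,Val,22.2,1.4,3
Champsocephalus gunnari,Val,21.5,0.9,10
Euphausia superba,Lys,2.1,0.8,10
Themisto gaudichaudii,Lys,1.2,1.5,3
Euphausia frigida,Lys,2.9,0.4,3
Antarctomysis maxima,Lys,0.8,1.0,3
Electrona antarctica,Lys,0.2,2.0,3
Champsocephalus gunnari,Lys,2.5,1.3,10
Euphausia superba,Met,-1.3,1.7,10
Themisto gaudichaudii,Met,3.7,0.6,3
Euphausia frigida,Met,0.7,0.9,3
Antarctomysis maxima,Met,4.2,1.0,3
Electrona antarctica,Met,2.8,2.6,3
Champsocephalus gunnari,Met,1.4,0.9,10
Euphausia superba,Phe,1.7,1.0,10
Themisto gaudichaudii,Phe,2.6,1.0,3
Euphausia frigida,Phe,1.5,1.3,3
Antarctomysis maxima,Phe,1.8,0.6,3
Electrona antarctica,Phe,0.8,0.7,3
Champsocephalus gunnari,Phe,1.3,0.8,10
Euphausia superba,Tyr,5.0,1.4,10
Themisto gaudichaudii,Tyr,5.1,0.9,3
Euphausia frigida,Tyr,6.4,1.0,3
Antarctomysis maxima,Tyr,5.1,0.9,3
Electrona antarctica,Tyr,6.1,1.3,3
Champsocephalus gunnari,Tyr,6.3,1.3,10
Euphausia superba,Ser,-0.9,2.7,10
Themisto gaudichaudii,Ser,3.7,1.3,3
Euphausia frigida,Ser,2.3,0.5,3
Antarctomysis maxima,Ser,3.7,1.3,3
Electrona antarctica,Ser,2.7,1.1,3
Champsocephalus gunnari,Ser,-3.9,0.9,10
Euphausia superba,Thr,-11.9,1.4,10
Themisto gaudichaudii,Thr,-17.9,2.2,3
Euphausia frigida,Thr,-11.0,1.0,3
Antarctomysis maxima,Thr,-17.9,2.2,3
Electrona antarctica,Thr,-15.9,0.7,3
Champsocephalus gunnari,Thr,-19.0,0.8,10
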