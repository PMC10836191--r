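drug,strength_mg,design
rosuvastatin,5,1
rosuvastatin,20,1
lisinopril,5,1
lisinopril,20,1
hydrochlorothiazide,12.5,1
hydrochlorothiazide,25,1
acetylsalicylic_acid,81,1
isoniazid,50,2
ethambutol,50,2
rifampicin,50,2
pyrazinamide,50,2
prednisone,2.5,2
prednisone,10,2
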