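drug,Q,time_min,note
rosuvastatin,75,30,
lisinopril,80,30,
hydrochlorothiazide,60,60,
acetylsalicylic_acid,80,30,
isoniazid,80,45,
ethambutol,75,45,transcribed from a line printed under the name isoniazid (duplicate); presumed ethambutol
rifampicin,75,45,
pyrazinamide,75,45,
prednisone,80,30,
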