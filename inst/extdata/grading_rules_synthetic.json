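[{"analyte":"alat","direction":"high","lln":0,"uln":45,"g1":135,"g2":225,"g3":900,"g4":1800},{"analyte":"asat","direction":"high","lln":0,"uln":40,"g1":120,"g2":200,"g3":800,"g4":1600},{"analyte":"ggt","direction":"high","lln":0,"uln":55,"g1":137.5,"g2":275,"g3":1100,"g4":2200},{"analyte":"alp","direction":"high","lln":30,"uln":120,"g1":300,"g2":600,"g3":2400,"g4":4800},{"analyte":"bilirubin","direction":"high","lln":0,"uln":21,"g1":31.5,"g2":63,"g3":210,"g4":420},{"analyte":"creatinine","direction":"high","lln":45,"uln":90,"g1":135,"g2":270,"g3":540,"g4":1080},{"analyte":"urea","direction":"high","lln":2.5,"uln":7.5,"g1":11.25,"g2":22.5,"g3":45,"g4":90},{"analyte":"mcv","direction":"high","lln":80,"uln":100,"g1":105,"g2":115,"g3":130,"g4":150},{"analyte":"albumin","direction":"low","lln":35,"uln":50,"g1":34,"g2":30,"g3":20,"g4":15},{"analyte":"haemoglobin","direction":"low","lln":120,"uln":160,"g1":100,"g2":80,"g3":65,"g4":50},{"analyte":"thrombocytes","direction":"low","lln":150,"uln":400,"g1":75,"g2":50,"g3":25,"g4":10},{"analyte":"leukocytes","direction":"low","lln":4,"uln":10,"g1":3,"g2":2,"g3":1,"g4":0.5},{"analyte":"neutrophils","direction":"low","lln":1.8,"uln":7.5,"g1":1.5,"g2":1,"g3":0.5,"g4":0.2},{"analyte":"lymphocytes","direction":"low","lln":1,"uln":4,"g1":0.8,"g2":0.5,"g3":0.25,"g4":0.1},{"analyte":"egfr","direction":"low","lln":60,"uln":120,"g1":59,"g2":45,"g3":30,"g4":15}]
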