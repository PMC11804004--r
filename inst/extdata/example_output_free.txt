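1. Diseases:
- Fever
- Sub-Saharan origin (assumed geographical disease association)
- Eosinophilia
- Renal hydatid disease (also known as hydatid cyst or echinococcosis)

2. Symptoms:
- Sweating
- Fever
- Left lumbar pain
- Heaviness in the left flank
- Dysuria (painful urination)
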