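Here are the entities of types disease, symptom, and medical procedure identified in the clinical document:

* Diseases: [renal hydatid disease;]
* Symptoms: [sweating; fever; left lumbar pain; heaviness in the left flank; dysuria; occasional fever; voiding symptoms; acceptable urinary stream; night-time voiding once and daytime voiding every 3–4 hours with a feeling of complete emptiness]
* Medical procedures: [physical examination; rectal examination; complementary tests; X-ray of the genito-urinary tract; renal ultrasound; abdominopelvic CT scan; echinococcus/hemag antibody serology; MRI; surgery; course of Albendazole; left nephroureterectomy]

Note that some of the symptoms are mentioned more than once in the document, but I have only included each symptom once in the list. Also, some of the medical procedures are not specific to this case, and could be part of a general clinical workup, but I have included them for completeness.
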