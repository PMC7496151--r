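lesion_term,severity
hyperplasia,1
metaplasia,1
dysplasia,1
foci of cellular alteration,1
basophilic focus,1
eosinophilic focus,1
clear cell focus,1
atypical hyperplasia,1
squamous metaplasia,1
adenoma,2
papilloma,2
fibroma,2
fibroadenoma,2
adenomatous polyp,2
polyp,2
lipoma,2
hemangioma,2
keratoacanthoma,2
pheochromocytoma,2
benign tumor,2
benign tumors,2
carcinoma,3
adenocarcinoma,3
squamous cell carcinoma,3
hepatocellular carcinoma,3
sarcoma,3
fibrosarcoma,3
osteosarcoma,3
hemangiosarcoma,3
mesothelioma,3
malignant lymphoma,3
leukemia,3
malignant pheochromocytoma,3
malignant tumor,3
malignant tumors,3
adenoma or carcinoma,3
carcinoma or adenoma,3
metastasizing carcinoma,4
metastasizing sarcoma,4
metastasizing tumors,4
metastasizing malignant tumors,4
malignant tumors in different organs,4
multiple organ malignancy,4
disseminated carcinoma,4
tumor-bearing animals,5
tumor bearing animals,5
animals with tumors,5
all tumors,5
total tumor-bearing animals,5
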