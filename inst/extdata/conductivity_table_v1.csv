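canonical_label,aliases,sigma_S_per_m,source
adrenal_gland,epididymis;hypophysis;pancreas;stomach;stomach_lumen;small_intestine;small_intestine_lumen;thymus;thyroid_gland;esophagus;esophagus_lumen,0.51113,tissue_database
internal_air,pharynx;trachea_lumen,0,tissue_database
artery,vein;blood_vessel;heart_lumen;penis,0.7,tissue_database
bladder,,0.202783,tissue_database
bone,mandible;marrow_red;patella;skull;teeth;vertebrae,0.020028,tissue_database
brain_grey_matter,hippocampus;hypothalamus;pineal_body;thalamus,0.027512,tissue_database
brain_white_matter,anterior_commissura;posterior_commissura,0.027656,tissue_database
breast,,0.2617535,tissue_database
bronchi,bronchi_lumen;ureter_urethra,0.25055,tissue_database
cartilage,ear_cartilage;intervertebral_disk;larynx;meniscus;trachea,0.16113,tissue_database
cerebellum,,0.047512,tissue_database
cerebrospinal_fluid,csf,2,tissue_database
connective_tissue,,0.1215635,tissue_database
cornea,,0.4113,tissue_database
muscle,diaphragm,0.201967,tissue_database
skin,ear_skin;scalp,0.012147,tissue_database
eye_lens,ovary,0.3113,tissue_database
eye_sclera,,0.501392,tissue_database
eye_vitreous_humor,,1.5,tissue_database
fat,subcutaneous_adipose_tissue;sat;fat_sat,0.012207,tissue_database
gallbladder,,0.9,tissue_database
heart_muscle,,0.053677,tissue_database
kidney_cortex,kidney_medulla,0.0544105,tissue_database
large_intestine,large_intestine_lumen;vagina,0.0122052,tissue_database
liver,,0.027714,tissue_database
lung,,0.120847,tissue_database
medulla_oblongata,midbrain;pons;brainstem,0.027584,tissue_database
mucosa,,0.0004,tissue_database
nerve,spinal_cord,0.017126,tissue_database
prostate,testis,0.41113,tissue_database
spleen,,0.0395962,tissue_database
tendon_ligament,,0.250922,tissue_database
tongue,,0.26113,tissue_database
uterus,,0.201296,tissue_database
electrode_pad,,5.9e7,electrode_model
sponge,,0.3,electrode_model
air,,0,electrode_model
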