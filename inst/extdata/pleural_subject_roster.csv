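subject_id,class_label,diagnosis
lung_01,lung_cancer,lung cancer
lung_02,lung_cancer,lung cancer
lung_03,lung_cancer,lung cancer
lung_04,lung_cancer,lung cancer
lung_05,lung_cancer,lung cancer
lung_06,lung_cancer,lung cancer
lung_07,lung_cancer,lung cancer
lung_08,lung_cancer,lung cancer
lung_09,lung_cancer,lung cancer
lung_10,lung_cancer,lung cancer
lung_11,lung_cancer,lung cancer
lung_12,lung_cancer,lung cancer
lung_13,lung_cancer,lung cancer
lung_14,lung_cancer,lung cancer
lung_15,lung_cancer,lung cancer
other_01,other_cancer,breast cancer
other_02,other_cancer,ovarian cancer
other_03,other_cancer,peritoneal cancer
other_04,other_cancer,malignant mesothelioma
other_05,other_cancer,malignant mesothelioma
other_06,other_cancer,multiple myeloma
other_07,other_cancer,lymphoma
control_01,control,exudate
control_02,control,exudate
control_03,control,exudate
control_04,control,exudate
control_05,control,exudate
control_06,control,exudate
control_07,control,exudate
control_08,control,exudate
control_09,control,transudate
control_10,control,transudate
control_11,control,transudate
control_12,control,transudate
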