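model,term,coefficient,centering,source
brock,intercept,-6.7892,,"McWilliams et al. NEJM 2013;369:910-919, Table: full model with spiculation (model 2b)"
brock,age_per_year,0.0287,62,"McWilliams 2013, full model with spiculation: per year of age, centred at 62"
brock,sex_female,0.6011,,"McWilliams 2013, full model with spiculation: female sex indicator"
brock,family_history,0.2961,,"McWilliams 2013, full model with spiculation: family history of lung cancer"
brock,emphysema,0.2953,,"McWilliams 2013, full model with spiculation: emphysema on CT"
brock,size_transform,-5.3854,1.58113883,"McWilliams 2013, full model with spiculation: (size_mm/10)^-0.5 centred at 1.58113883"
brock,density_nonsolid,-0.1276,,"McWilliams 2013, full model with spiculation: non-solid/GGO vs solid"
brock,density_partsolid,0.377,,"McWilliams 2013, full model with spiculation: part-solid vs solid"
brock,upper_lobe,0.6581,,"McWilliams 2013, full model with spiculation: upper-lobe location"
brock,nodule_count_per_nodule,-0.0824,4,"McWilliams 2013, full model with spiculation: per additional nodule, centred at 4"
brock,spiculation,0.7729,,"McWilliams 2013, full model with spiculation: spiculation indicator"
herder,intercept,-4.739,,"Herder et al. Chest 2005;128:2490-2496: PET-adjusted Mayo model"
herder,age_per_year,0.0391,,"Herder 2005 (Mayo covariate): per year of age"
herder,smoker_ever,0.7917,,"Herder 2005 (Mayo covariate): current or former smoker"
herder,extrathoracic_cancer,1.3388,,"Herder 2005 (Mayo covariate): extrathoracic cancer >=5 years before"
herder,diameter_per_mm,0.1274,,"Herder 2005 (Mayo covariate): per mm nodule diameter"
herder,spiculation,1.0407,,"Herder 2005 (Mayo covariate): spiculated margin"
herder,upper_lobe,0.7838,,"Herder 2005 (Mayo covariate): upper-lobe location"
herder,pet_absent,0,,"Herder 2005: FDG avidity reference category (none)"
herder,pet_faint,2.322,,"Herder 2005: faint FDG avidity"
herder,pet_moderate,4.617,,"Herder 2005: moderate FDG avidity"
herder,pet_intense,4.771,,"Herder 2005: intense FDG avidity"
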