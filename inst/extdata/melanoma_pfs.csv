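trial_id,author_year,treatment,n,dose_label,hr,ci_low,ci_high,ae_any,ae_high,outcome
weber2015,Weber 2015,NIV,272,3 mg/kg q2w,0.82,0.32,2.05,,,PFS
weber2015,Weber 2015,CHE,133,investigator choice,1,,,,,PFS
ribas2015,Ribas 2015,PEM,180,2 mg/kg,0.57,0.45,0.73,,,PFS
ribas2015,Ribas 2015,PEM,181,10 mg/kg,0.50,0.39,0.64,,,PFS
ribas2015,Ribas 2015,CHE,179,investigator choice,1,,,,,PFS
larkin2015,Larkin 2015,NIV,316,3 mg/kg q2w,0.57,0.43,0.76,,,PFS
larkin2015,Larkin 2015,IPI_NIV,314,3 mg/kg + 1 mg/kg,0.42,0.31,0.57,,,PFS
larkin2015,Larkin 2015,IPI,315,3 mg/kg q3w,1,,,,,PFS
postow2015,Postow 2015,IPI_NIV,95,3 mg/kg + 1 mg/kg,0.40,0.23,0.68,,,PFS
postow2015,Postow 2015,IPI,47,3 mg/kg q3w,1,,,,,PFS
robert2015p,Robert 2015 (pembrolizumab),PEM,279,10 mg/kg q2w,0.58,0.46,0.72,,,PFS
robert2015p,Robert 2015 (pembrolizumab),PEM,277,10 mg/kg q3w,0.58,0.47,0.72,,,PFS
robert2015p,Robert 2015 (pembrolizumab),IPI,278,3 mg/kg q3w,1,,,,,PFS
robert2015n,Robert 2015 (nivolumab),NIV,210,3 mg/kg q3w,0.43,0.34,0.56,,,PFS
robert2015n,Robert 2015 (nivolumab),CHE,208,dacarbazine,1,,,,,PFS
hodi2014,Hodi 2014,IPI_SAR,123,10 mg/kg q3w + sargramostim,0.87,0.64,1.18,,,PFS
hodi2014,Hodi 2014,IPI,122,10 mg/kg q3w,1,,,,,PFS
ribas2013,Ribas 2013,TRE,328,15 mg/kg q90d,0.55,0.39,0.76,,,PFS
ribas2013,Ribas 2013,CHE,327,investigator choice,1,,,,,PFS
robert2011,Robert 2011,IPI_CHE,250,10 mg/kg q3w + dacarbazine,0.76,0.63,0.93,,,PFS
robert2011,Robert 2011,CHE,252,dacarbazine + placebo,1,,,,,PFS
hodi2010,Hodi 2010,IPI_GP100,403,3 mg/kg q3w + gp100,0.81,0.74,0.92,,,PFS
hodi2010,Hodi 2010,IPI,137,3 mg/kg q3w,0.64,0.56,0.78,,,PFS
hodi2010,Hodi 2010,GP100,136,vaccine,1,,,,,PFS
hersh2011,Hersh 2011,IPI_CHE,35,3 mg/kg q4w + dacarbazine,,,,,,PFS
hersh2011,Hersh 2011,IPI,37,3 mg/kg q4w,,,,,,PFS
weber2009,Weber 2009,IPI_BUD,58,10 mg/kg q3w + budesonide,,,,,,PFS
weber2009,Weber 2009,IPI,57,10 mg/kg q3w + placebo,,,,,,PFS
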