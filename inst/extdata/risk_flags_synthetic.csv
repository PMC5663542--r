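trial_id,low_risk
weber2015,FALSE
ribas2015,FALSE
larkin2015,TRUE
postow2015,TRUE
robert2015p,TRUE
robert2015n,TRUE
hodi2014,TRUE
ribas2013,FALSE
robert2011,TRUE
hodi2010,TRUE
hersh2011,TRUE
weber2009,TRUE
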