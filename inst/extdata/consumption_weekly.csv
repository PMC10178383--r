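age_group,milk_type,mean_g_per_kgbw_week,p95_g_per_kgbw_week
infants,semi-skimmed,178.5,555.87
infants,whole,234.15,557.89
toddlers,semi-skimmed,120.68,272.86
toddlers,whole,128.1,299.32
children,skimmed,53.76,141.19
children,semi-skimmed,58.08,135.1
children,whole,59.08,156.1
adolescents,skimmed,20.65,58.66
adolescents,semi-skimmed,22.75,47.39
adolescents,whole,17.08,45.71
adults,skimmed,11.13,25.41
adults,semi-skimmed,14.42,29.33
adults,whole,8.12,23.45
elderly,skimmed,10.50,25.41
elderly,semi-skimmed,16.87,30.66
elderly,whole,9.24,27.23
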