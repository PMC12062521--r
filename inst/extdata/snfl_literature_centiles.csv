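# Static documentation table: published upper reference values of serum/plasma
# NfL (pg/ml) by age across selected healthy-cohort studies, all measured on
# the Simoa platform. Not consumed by any computation in this package.
study,n,site,analysis,cutoff_definition,nfl_age20,nfl_age30,nfl_age40,nfl_age50,nfl_age60
Chen et al.,146,China,subgroup descriptive analysis,P95,8.4,9.2,22.2,34.1,68.3
Hviid et al.,342,Denmark,linear regression on log NfL,P97.5,7.4,9.9,13.1,17.5,23.3
Bornhorst et al.,1100,USA,linear regression on log NfL,P97.5,8.4,11.4,15.4,20.8,28.0
Benkert et al.,5390,"USA, Netherlands, Switzerland, Germany",GAMLSS and Z-score derivation,Z>2.0 (P97.72),8.5,11.5,14.2,18.1,23.8
Vermunt et al.,833,Netherlands,quantile regression on log NfL,P95,9.0,10.0,12.0,14.0,19.0
Thai reference cohort,223,Thailand,GAMLSS and Z-score derivation,P97.5,8.2,9.9,11.7,14.6,20.8
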