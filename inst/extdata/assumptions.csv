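label,pattern
missing completely at random,"missing completely at random|\bmcar\b"
normality of residuals,"normalit(y|ies) of( the)? residuals|residuals? (are|were) normally distributed|normally distributed residuals|residual normality"
homogeneity of variances,"homogeneity of variances?|variance homogeneity|homogenous variances"
independence of errors,"independen(ce|t) (of )?(the )?errors?|uncorrelated errors"
measurement invariance,"measurement invariance|measurement equivalence"
multivariate normal,"multivariate normal|multinormal"
missing at random,"missing at random"
proportional hazards,"proportional hazards?"
proportional odds,"proportional odds"
random sampling,"random sampl(e|ing)|randomly sampled"
equal variances,"equal(ity of)? variances?"
homoscedasticity,"homoscedastic|homoskedastic"
multicollinearity,"multi-?collinearit|collinearity"
autocorrelation,"auto-?correlat"
normal distribution,"normal(ly)? distribut|normality|univariate normal"
independency,"independency|independen(ce|t) (of )?(the )?(observations?|measurements?|cases|samples?|data)"
sphericity,"sphericity"
linearity,"linearity|linear relationship"
exchangeability,"exchangeab"
stationarity,"stationarity|stationary (series|process)"
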