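label,pattern
Descriptive statistics,"descriptive statistics|descriptive analysis|descriptives"
Distribution fitting,"distributional analysis|distribution analysis|distribution fitting"
Inter-rater agreement,"inter rater reliability|kappa|intraclass correlation|intra class correlation"
Pearson's correlation coefficient,"pearson correlation|pearson product|product moment|zero order correlation|(^| )correlation$"
Correlation comparison test,"correlation comparison|coefficient comparison"
Spearman's correlation coefficient,"spearman corr|spearman brown|spearman coef|spearman rank|spearman rho"
Other nominal/ordinal correlation measures,"gamma|cramer v|somer d|contingency table analysis|contingency coef"
Pearson's Chi-square,"^chi square|[^d] chi square"
Other tests of contingency tables and proportions,"fisher exact|fisher z|mcnemar|cochran q|z statistic"
Mann-Whitney U test,"mann whitney|mannwhitney|u test"
Wilcoxon signed-rank test,"wilcoxon|signed rank"
Kruskal-Wallis test,"kruskal\b|wallis\b"
Friedman test,"friedman test"
One sample t-test,"one sample t test|single sample t test"
Independent t-test,"^t test$|[^n][^e] t test|independent t test|two sample t test"
Paired t-test,"paired samples t test|paired sample t test|paired t test"
ANOVA,"(^| )anova"
ANCOVA,"(^| )ancova"
MANOVA/MANCOVA,"manova|mancova"
Regression analysis,"regression"
Multilevel regression,"multilevel.*?regression|hierarchic.*?regression|mixed.*?regression"
Multivariate regression,"multivariate.*?regres|multiple.*?regres"
Poisson regression,"poisson regression"
Logistic regression,"log.*?regression"
Multilevel logistic regression,"multilevel logistic|logistic multilevel"
Multinomial/ordinal regression,"multinom.*?regres|ordin.*?regres"
Generalized estimation equation,"\bgee\b|generalized estimation equation"
Path analysis,"path analysis|path model|path coefficient|path estimate|structural equation"
Multilevel SEM,"multilevel structural equation"
Growth curve modeling,"growth curve|growth model"
Multilevel growth curve modeling,"multilevel growth|multigroup.*?growth"
Confirmatory factor analysis,"confirmatory factor"
Exploratory factor analysis,"exploratory factor"
Cronbach's alpha,"cronbach alpha|reliability coeff|cronbach coeff"
McDonald's omega,"mcdonald|mc donald|omega coef|omega estimate"
Test-retest reliability,"test retest reliability|test retest corr"
Convergent/discriminant validity indexes,"convergent validity|discriminant validity|[^a-z]ave |^ave |msv"
Sensitivity and specificity measures,"sensitivity|specificity|specifity"
Item analysis: classical test theory,"item analysis|items analysis"
Item analysis: item response theory,"item response analysis|dif analysis"
Cluster analysis,"cluster analysis"
ROC curve analysis,"roc curve|receiver operating"
Markov models,"markov|marcov"
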