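type,canonical,pattern
author,Bonferroni,"bonn?ff?err?onn?i"
author,Tukey,"tuc?key"
author,Holm,"\bholms?\b"
author,Hochberg,"hochberg"
author,Scheffé,"scheff?[eé]"
author,Benjamini,"benjamini"
author,Duncan,"duncan"
author,Keuls,"keuls?"
author,Newman,"newman"
author,Fisher LSD,"fisher|\blsd\b|least significant difference"
author,Sidak,"[sš]id[aá]k|sidack"
author,Dunnett,"dunn?ett?\b"
procedure,family-wise error rate,"family-?wise error|familywise error"
procedure,false discovery rate,"false discovery rate|\bfdr\b"
procedure,per-comparison error correction,"per-?comparison error"
procedure,stepwise p-adjustment,"step-?wise.{0,12}adjust"
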