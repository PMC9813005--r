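<?xml version="1.0" encoding="UTF-8"?>
<article dtd-version="1.1">
  <front>
    <article-meta>
      <article-id>example-0001</article-id>
      <title-group>
        <article-title>Context effects on evaluative judgment: an example article</article-title>
      </title-group>
      <abstract>
        <p>We examined evaluative judgment under varying context in a laboratory sample.</p>
      </abstract>
    </article-meta>
  </front>
  <body>
    <sec>
      <title>Introduction</title>
      <p>Prior work has examined how context shapes judgment.</p>
    </sec>
    <sec>
      <title>Methods</title>
      <sec>
        <title>Participants</title>
        <p>Forty adults took part in exchange for course credit.
           Observations more than 2 standard deviations from the sample mean
           were excluded as outliers.</p>
      </sec>
      <sec>
        <title>Analysis plan</title>
        <p>The α-level was set to 0.05. A statistical power of 0.8 was
           targeted. A repeated measures anova was conducted for the primary
           comparison. All pairwise p-values were adjusted with the
           Bonferroni procedure. The sphericity assumption was checked in
           advance. All computations were carried out in SPSS (version 25).</p>
      </sec>
    </sec>
    <sec>
      <title>Results</title>
      <p>The condition × group interaction was reliable. We report 95%
         confidence intervals for all effects.</p>
    </sec>
    <sec>
      <title>Discussion</title>
      <p>The findings are discussed with respect to contextual accounts.</p>
    </sec>
    <fig>
      <caption><p>Figure 1. Average responses by condition and group.</p></caption>
    </fig>
  </body>
  <back>
    <ref-list>
      <ref>Author, A. (2017). A treatise on measurement. Journal of Things, 1, 1-10.</ref>
    </ref-list>
  </back>
</article>
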