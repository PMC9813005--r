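{
  "alpha": {
    "explicit": [
      "The α-level was set to {v}.",
      "An alpha level of {v} was adopted.",
      "The significance criterion was {v}."
    ],
    "p_threshold": [
      "Results with p-values < {v} were considered significant.",
      "Effects were regarded as significant at p < {v}."
    ],
    "ci": [
      "{pct}% confidence intervals were computed around each estimate.",
      "We report {pct}% confidence intervals for all effects."
    ],
    "fraction": [
      "The α-level was set to {v}/{k} to account for the planned contrasts."
    ]
  },
  "power": {
    "direct": [
      "A statistical power of {v} was targeted.",
      "The achieved power was {v}."
    ],
    "beta": [
      "We fixed β = {b} for the planned comparisons."
    ],
    "interval": [
      "The design achieved a power ranging between {v} and {v2}."
    ]
  },
  "correction": [
    "All pairwise p-values were adjusted with the {author} procedure.",
    "We applied a {author} correction for the planned contrasts.",
    "Post-hoc comparisons used the {author} criterion."
  ],
  "interaction": {
    "interaction": [
      "The condition × group interaction was reliable.",
      "There was a clear interaction between condition and group."
    ],
    "mediator": [
      "The effect of condition on the outcome was mediated by perceived control.",
      "A mediating role of perceived control emerged."
    ],
    "moderator": [
      "Age moderated the association between condition and the outcome.",
      "The pattern points to a moderating influence of age."
    ]
  },
  "direction": {
    "one_sided": [
      "All primary comparisons were one-tailed.",
      "Directional hypotheses were evaluated with one-sided criteria."
    ],
    "two_sided": [
      "All comparisons were two-sided.",
      "We report two-tailed probabilities throughout."
    ]
  },
  "outlier": [
    "Observations more than {v} standard deviations from the sample mean were excluded as outliers.",
    "Participants with extreme scores (±{v} SD) were removed."
  ],
  "assumption": [
    "The {label} assumption was checked in advance.",
    "We verified the assumption of {label} prior to the main computations."
  ],
  "software": [
    "All computations were carried out in {mention}.",
    "Data were processed with {mention}."
  ],
  "method": [
    "We conducted {art} {phrase} for the primary comparison.",
    "{Art} {phrase} was run on the outcome scores.",
    "We then fitted {art} {phrase} to the responses."
  ],
  "filler": [
    "Participants completed the task in a quiet laboratory room.",
    "Stimuli were presented on a grey background in a fixed sequence.",
    "Each trial began with a central cue that stayed visible until a response was given.",
    "The session lasted about forty minutes including short breaks.",
    "Instructions were identical across groups.",
    "Data collection took place over the spring term.",
    "Responses were recorded with a keyboard.",
    "The questionnaire covered demographic information.",
    "Group averages are displayed in the figures."
  ],
  "abstract": [
    "We investigated how contextual cues shape evaluative judgments in adults.",
    "This article reports a laboratory investigation of attention and evaluative judgment."
  ]
}
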