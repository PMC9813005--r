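name,pattern
SPSS,"SPSS|PASW"
Mplus,"(?i)\bm-?plus\b"
PROCESS MACRO,"(?i)process macro|PROCESS\b.{0,12}(?i:macro)|(?i)macro process|Hayes'?s? PROCESS"
AMOS,"\bAMOS\b|\bAmos\b"
G*Power,"(?i)g ?\* ?power|g-?power\b"
MATLAB,"(?i)\bmatlab\b"
Stata,"(?i)\bstata\b"
SAS,"\bSAS\b"
R,"R version [0-9]|\bR [0-9]\.[0-9]|R Core Team|(?i)the R (environment|language|software|project|statistical)|R statistical (software|environment)"
RStudio,"(?i)r-?studio"
HLM,"\bHLM\b"
EQS,"\bEQS\b"
JASP,"\bJASP\b"
Excel,"(?i)\bexcel\b"
LISREL,"(?i)\blisrel\b"
FACTOR,"FACTOR (program|software|[0-9])|program FACTOR"
Python,"(?i)\bpython\b"
Psychtoolbox,"(?i)psych ?toolbox"
AcqKnowledge,"(?i)acq ?knowledge"
MLwiN,"(?i)\bmlwin\b"
WarpPLS,"(?i)warp ?pls"
Statistica,"(?i)\bstatistica\b"
Praat,"(?i)\bpraat\b"
ImageJ,"(?i)image ?j\b"
TimeStudio,"(?i)time ?studio"
jamovi,"(?i)\bjamovi\b"
JMP,"\bJMP\b"
Minitab,"(?i)\bminitab\b"
Mathematica,"(?i)\bmathematica\b"
E-Prime,"(?i)\be-?prime\b"
SYSTAT,"(?i)\bsystat\b"
GraphPad Prism,"(?i)graph ?pad|\bprism [0-9]"
WinBUGS,"(?i)\bwinbugs\b"
OpenBUGS,"(?i)\bopenbugs\b"
JAGS,"\bJAGS\b"
Stan,"\bStan\b|\bRStan\b|(?i)\brstan\b"
Comprehensive Meta-Analysis,"(?i)comprehensive meta-?analysis|\bCMA\b"
RevMan,"(?i)\brevman\b|review manager"
SmartPLS,"(?i)smart ?-?pls"
Latent GOLD,"(?i)latent ?gold"
IRTPRO,"(?i)\birtpro\b"
BILOG,"(?i)\bbilog\b"
MULTILOG,"(?i)\bmultilog\b"
PARSCALE,"(?i)\bparscale\b"
flexMIRT,"(?i)\bflexmirt\b"
Winsteps,"(?i)\bwinsteps\b"
Octave,"(?i)\boctave\b"
Julia,"\bJulia [0-9]|(?i)julia (language|programming)"
SUDAAN,"(?i)\bsudaan\b"
Epi Info,"(?i)\bepi ?info\b"
SigmaPlot,"(?i)\bsigmaplot\b"
SigmaStat,"(?i)\bsigmastat\b"
NCSS,"\bNCSS\b"
StatXact,"(?i)\bstatxact\b"
XLSTAT,"(?i)\bxlstat\b"
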