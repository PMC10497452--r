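software,structure,comparison,sem_pct,sdc_pct
FastSurfer,brain,within,0.51,1.43
FastSurfer,brain,between,4.39,12.17
FreeSurfer,brain,within,0.56,1.56
FreeSurfer,brain,between,1.96,5.43
SAMSEG,brain,within,0.37,1.02
SAMSEG,brain,between,2.07,5.73
FSL,brain,within,1.32,3.67
FSL,brain,between,2.08,5.77
CAT12,brain,within,0.92,2.55
CAT12,brain,between,2.75,7.62
SynthSeg,brain,within,0.45,1.26
SynthSeg,brain,between,1.98,5.48
FastSurfer,wm,within,0.62,1.70
FastSurfer,wm,between,6.78,18.78
FreeSurfer,wm,within,0.85,2.35
FreeSurfer,wm,between,4.12,11.43
SAMSEG,wm,within,0.53,1.48
SAMSEG,wm,between,2.39,6.61
FSL,wm,within,1.55,4.29
FSL,wm,between,4.35,12.05
CAT12,wm,within,1.12,3.11
CAT12,wm,between,3.90,10.82
SynthSeg,wm,within,0.60,1.66
SynthSeg,wm,between,2.38,6.61
FastSurfer,csf,within,1.84,5.11
FastSurfer,csf,between,7.06,19.57
FreeSurfer,csf,within,5.25,14.55
FreeSurfer,csf,between,8.59,23.81
SAMSEG,csf,within,0.97,2.68
SAMSEG,csf,between,5.30,14.69
FSL,csf,within,1.63,4.52
FSL,csf,between,5.42,15.03
CAT12,csf,within,2.79,7.72
CAT12,csf,between,8.33,23.09
SynthSeg,csf,within,0.59,1.63
SynthSeg,csf,between,3.05,8.45
FastSurfer,gm,within,0.61,1.69
FastSurfer,gm,between,4.07,11.27
FreeSurfer,gm,within,0.68,1.88
FreeSurfer,gm,between,2.59,7.17
SAMSEG,gm,within,0.49,1.36
SAMSEG,gm,between,2.20,6.10
FSL,gm,within,1.51,4.20
FSL,gm,between,4.02,11.15
CAT12,gm,within,0.97,2.70
CAT12,gm,between,2.71,7.52
SynthSeg,gm,within,0.45,1.25
SynthSeg,gm,between,1.90,5.27
FastSurfer,thalamus,within,1.09,3.01
FastSurfer,thalamus,between,2.84,7.88
FreeSurfer,thalamus,within,3.45,9.57
FreeSurfer,thalamus,between,5.27,14.62
SAMSEG,thalamus,within,0.69,1.92
SAMSEG,thalamus,between,1.76,4.89
FSL,thalamus,within,1.66,4.61
FSL,thalamus,between,3.02,8.36
CAT12,thalamus,within,3.28,9.08
CAT12,thalamus,between,10.55,29.25
SynthSeg,thalamus,within,0.99,2.76
SynthSeg,thalamus,between,1.75,4.83
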