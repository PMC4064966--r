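channel,replicate,window,accuracy
Fp1,K3,3-4 s,0.52
Fp1,K3,4-5 s,0.74
Fp1,K3,5-6 s,0.58
Fp1,K3,6-7 s,0.58
Fp1,K6,3-4 s,0.63
Fp1,K6,4-5 s,0.83
Fp1,K6,5-6 s,0.63
Fp1,K6,6-7 s,0.63
Fp1,L1,3-4 s,0.55
Fp1,L1,4-5 s,0.58
Fp1,L1,5-6 s,0.56
Fp1,L1,6-7 s,0.78
Fpz,K3,3-4 s,0.53
Fpz,K3,4-5 s,0.6
Fpz,K3,5-6 s,0.64
Fpz,K3,6-7 s,0.58
Fpz,K6,3-4 s,0.55
Fpz,K6,4-5 s,0.83
Fpz,K6,5-6 s,0.53
Fpz,K6,6-7 s,0.63
Fpz,L1,3-4 s,0.78
Fpz,L1,4-5 s,0.58
Fpz,L1,5-6 s,0.67
Fpz,L1,6-7 s,0.54
Fp2,K3,3-4 s,0.56
Fp2,K3,4-5 s,0.64
Fp2,K3,5-6 s,0.73
Fp2,K3,6-7 s,0.67
Fp2,K6,3-4 s,0.63
Fp2,K6,4-5 s,0.78
Fp2,K6,5-6 s,0.51
Fp2,K6,6-7 s,0.63
Fp2,L1,3-4 s,0.55
Fp2,L1,4-5 s,0.75
Fp2,L1,5-6 s,0.67
Fp2,L1,6-7 s,0.67
C3,K3,3-4 s,0.64
C3,K3,4-5 s,0.85
C3,K3,5-6 s,0.69
C3,K3,6-7 s,0.64
C3,K6,3-4 s,0.56
C3,K6,4-5 s,0.73
C3,K6,5-6 s,0.5
C3,K6,6-7 s,0.63
C3,L1,3-4 s,0.5
C3,L1,4-5 s,0.58
C3,L1,5-6 s,0.67
C3,L1,6-7 s,0.67
Cz,K3,3-4 s,0.75
Cz,K3,4-5 s,0.6
Cz,K3,5-6 s,0.56
Cz,K3,6-7 s,0.56
Cz,K6,3-4 s,0.8
Cz,K6,4-5 s,0.6
Cz,K6,5-6 s,0.6
Cz,K6,6-7 s,0.57
Cz,L1,3-4 s,0.56
Cz,L1,4-5 s,0.67
Cz,L1,5-6 s,0.63
Cz,L1,6-7 s,0.75
C4,K3,3-4 s,0.71
C4,K3,4-5 s,0.64
C4,K3,5-6 s,0.67
C4,K3,6-7 s,0.7
C4,K6,3-4 s,0.88
C4,K6,4-5 s,0.63
C4,K6,5-6 s,0.63
C4,K6,6-7 s,0.63
C4,L1,3-4 s,0.56
C4,L1,4-5 s,0.5
C4,L1,5-6 s,0.63
C4,L1,6-7 s,0.71
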