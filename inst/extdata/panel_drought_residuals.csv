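cultivar,residual_dw,residual_dw_sem,residual_dw_letters,residual_fv_fm,residual_fv_fm_sem,residual_fv_fm_letters,residual_phi_psii_ef,residual_phi_psii_ef_sem,residual_phi_psii_ef_letters,n
C1,81.9,0.4,ab,93.7,2.4,abc,60.5,7.6,abc,10
C2,68.0,3.3,a,89.6,4.5,ab,28.6,5.6,ab,10
C3,74.8,4.4,ab,97.7,1.3,abc,46.5,6.7,abc,10
C4,107.9,6.3,c,99.3,1.9,bc,69.2,5.4,c,10
C5,94.9,6.9,bc,97.7,1.1,abc,48.5,3.8,abc,10
C6,90.0,2.1,abc,89.4,3.6,a,49.0,11.7,abc,10
C7,74.0,3.7,ab,98.8,0.9,bc,53.1,3.3,abc,10
C8,80.7,5.2,ab,99.4,0.9,bc,41.4,6.2,abc,10
C9,82.6,6.2,ab,102.6,0.8,c,66.1,1.9,bc,10
C10,67.9,5.0,a,88.9,1.8,a,26.8,2.9,a,10
C11,92.2,3.1,abc,102.2,1.4,c,69.3,7.8,c,10
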