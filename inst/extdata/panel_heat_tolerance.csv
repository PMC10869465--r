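cultivar,t_dec,t_dec_sem,t_dec_letters,phi_psii_resid,phi_psii_resid_sem,phi_psii_resid_letters,n
C1,53.5,1.0,cd,66.9,7.6,d,10
C2,49.0,0.6,ab,44.7,1.8,abcd,10
C3,46.0,1.3,ab,23.1,6.6,a,10
C4,54.0,0.6,d,64.8,7.4,cd,10
C5,49.5,0.5,bc,29.9,3.3,ab,10
C6,47.5,1.1,ab,41.6,6.1,abcd,10
C7,47.5,1.4,ab,50.1,8.2,abcd,10
C8,48.5,1.0,ab,58.0,6.5,bcd,10
C9,55.0,0.0,d,68.3,6.8,d,10
C10,45.5,0.5,ab,25.6,2.3,a,10
C11,45.0,0.8,a,35.3,7.2,abc,10
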