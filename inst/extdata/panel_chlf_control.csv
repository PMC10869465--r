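cultivar,fv_fm,fv_fm_sem,phi_psii_ef,phi_psii_ef_sem,npq_s,npq_s_sem,t_half_phi,t_half_phi_sem,npq_max,npq_max_sem,t_npq_max,t_npq_max_sem,n
C1,0.812,0.001,0.456,0.010,0.760,0.027,229.2,10.6,1.727,0.031,219.0,7.6,20
C2,0.813,0.001,0.558,0.008,0.532,0.019,167.2,8.1,1.415,0.043,160.5,7.3,20
C3,0.810,0.001,0.506,0.011,0.704,0.025,198.4,12.3,1.718,0.036,195.0,10.1,20
C4,0.810,0.001,0.499,0.010,0.742,0.036,231.5,8.9,1.739,0.028,226.5,7.7,20
C5,0.808,0.001,0.607,0.006,0.442,0.017,173.3,8.8,1.407,0.050,175.3,6.2,20
C6,0.808,0.001,0.513,0.013,0.775,0.045,154.5,11.2,1.701,0.051,186.0,7.1,20
C7,0.820,0.001,0.568,0.007,0.589,0.020,197.2,9.8,1.846,0.040,190.5,5.9,20
C8,0.812,0.001,0.506,0.013,0.659,0.025,113.7,5.6,1.306,0.036,136.5,10.1,20
C9,0.805,0.001,0.515,0.009,0.670,0.033,186.4,10.5,1.608,0.030,220.0,9.1,20
C10,0.812,0.001,0.577,0.007,0.471,0.018,104.9,6.4,1.244,0.033,147.0,6.5,20
C11,0.810,0.001,0.571,0.009,0.573,0.026,128.5,6.6,1.490,0.031,144.0,6.0,20
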