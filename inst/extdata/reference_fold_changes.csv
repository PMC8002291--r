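experiment,gene,condition,fold_mean,fold_sd,n
IBET151,CEBPD_SEAP,M1_DMSO,5.3,1.4,3
IBET151,CEBPD_SEAP,M1_IBET151,9.6,2.0,3
IBET151,CEBPD,M1_DMSO,4.8,1.0,3
IBET151,CEBPD,M1_IBET151,7.5,1.1,3
IBET151,IL6,M1_DMSO,6625.0,1045.0,3
IBET151,IL6,M1_IBET151,102.3,118.1,3
IBET151,CCL2,M1_DMSO,187.7,105.4,3
IBET151,CCL2,M1_IBET151,11.5,3.3,3
IBET151,IL1B,M1_DMSO,396.0,62.4,3
IBET151,IL1B,M1_IBET151,927.1,124.2,3
RO11_1464,CEBPD_SEAP,M1_DMSO,5.5,1.5,5
RO11_1464,CEBPD_SEAP,M1_RO11_1464,8.8,3.4,5
RO11_1464,CEBPD,M1_DMSO,6.3,2.8,5
RO11_1464,CEBPD,M1_RO11_1464,12.4,5.5,5
RO11_1464,IL6,M1_DMSO,12432.0,10092.0,5
RO11_1464,IL6,M1_RO11_1464,1364.0,1426.0,5
RO11_1464,CCL2,M1_DMSO,237.2,82.8,5
RO11_1464,CCL2,M1_RO11_1464,26.6,9.0,5
RO11_1464,IL1B,M1_DMSO,344.8,119.0,5
RO11_1464,IL1B,M1_RO11_1464,445.3,138.6,5
SAHA_TSA,CEBPD_SEAP,M1_DMSO,4.5,0.4,3
SAHA_TSA,CEBPD_SEAP,M1_TSA,6.4,1.3,3
SAHA_TSA,CEBPD_SEAP,M1_SAHA,6.8,1.3,3
SAHA_TSA,CEBPD,M1_DMSO,6.1,1.2,3
SAHA_TSA,CEBPD,M1_TSA,0.9,0.1,3
SAHA_TSA,CEBPD,M1_SAHA,1.1,0.2,3
SAHA_TSA,IL6,M1_DMSO,7617.0,1258.0,3
SAHA_TSA,IL6,M1_TSA,58.1,16.1,3
SAHA_TSA,IL6,M1_SAHA,68.7,20.1,3
SAHA_TSA,CCL2,M1_DMSO,114.9,33.4,3
SAHA_TSA,CCL2,M1_TSA,6.8,1.5,3
SAHA_TSA,CCL2,M1_SAHA,7.6,1.9,3
SAHA_TSA,IL1B,M1_DMSO,374.3,47.9,3
SAHA_TSA,IL1B,M1_TSA,492.5,67.1,3
SAHA_TSA,IL1B,M1_SAHA,501.9,83.6,3
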