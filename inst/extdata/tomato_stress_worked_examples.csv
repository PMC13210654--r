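date,group,swc_pct,ppv,dawn_max_um,dusk_min_um,mds_um,growth_arrest
2025-05-04,control,26,1.00,5451.73,5417.85,33.93,no
2025-05-04,drought,18.9,0.73,5506.64,5389.47,117.17,yes
2025-05-16,control,25.3,0.97,5872.02,5863.66,8.36,no
2025-05-16,drought,21.5,0.83,5902.91,5818.34,84.57,yes
2025-05-25,control,22.8,0.88,6079.35,6028.39,50.96,no
2025-05-25,drought,16.2,0.62,6106.67,6006.97,99.7,yes
2025-05-26,control,24.5,0.94,6110.12,6065.23,44.89,no
2025-05-27,drought,20.5,0.79,6120.33,6055.98,64.35,no
2025-05-28,drought,18.0,0.69,6125.76,6050.21,75.55,no
2025-05-29,drought,17.5,0.67,6130.45,6050.99,79.46,imminent
2025-05-30,drought,16.5,0.63,6135.10,6045.00,90.10,yes
2025-06-01,drought,19.2,0.74,5990.25,5925.80,64.45,no
2025-06-02,drought,17.0,0.65,6000.10,5930.50,69.60,no
2025-06-03,drought,15.8,0.61,6010.55,5935.10,75.45,imminent
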