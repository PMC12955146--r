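drug,alpha,beta,n_years
Tamoxifen,1198.5,0.0972,30
Avastin,2215.9,0.1211,20
Bleomycin,114.55,0.139,30
Paclitaxel,1526.4,0.1673,30
Vincristine,210.66,0.1706,30
Methotrexate,438.1,0.1853,30
Cisplatin,331.75,0.1859,30
Doxorubicin,922.11,0.208,30
Imatinib,661.54,0.2427,20
Docetaxel,174.39,0.267,25
Rituximab,243.38,0.2771,25
Trastuzumab,64.147,0.3025,25
Revlimid,67.908,0.5431,18
Lenalidomide,67.848,0.5432,18
Pembrolizumab,1.1524,0.8277,10
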