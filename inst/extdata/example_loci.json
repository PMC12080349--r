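[{"id":"L0001","subtype":"II-C","contig":"ctg_L0001","strand":"-","repeats":[{"start":325,"end":360},{"start":259,"end":294},{"start":193,"end":228},{"start":127,"end":162},{"start":61,"end":96}],"consensus":"AATGCTAGTGCTGCTGCAGCATAGTTCTTCCAATTC","tracrRNA":"CTATGCTGCAGCAGCACTAGCATTACAGCTCATCTCGGATAAGTAGGTCTTCTCGTACTAATGCGAATGCCCCCAAATTGCTGA"},{"id":"L0002","subtype":"II-C","contig":"ctg_L0002","strand":"-","repeats":[{"start":523,"end":558},{"start":457,"end":492},{"start":391,"end":426},{"start":325,"end":360},{"start":259,"end":294},{"start":193,"end":228},{"start":127,"end":162},{"start":61,"end":96}],"consensus":"CTTAGCTAATCTAACCGATGCCCGGCATAACTATCC","tracrRNA":"CGGGCATCGGTTAGATTAGCTAAGGGCCCCCAACTGGTCCTTAACCCCAATCTACGTCTCTCAATTTAAGAGAAGAGTACGCCC"}]
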