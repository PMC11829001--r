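e37975dabd51d4120856749efe871ff7  benchmark_table3.tsv
6fc90e1fa8da269a9bca8df65a11e80f  benchmark_table4.tsv
7e8bc9a3babc3f18b2354aae3e6f293f  benchmark_table5.tsv
9780ab4b25e38c94d11f8c70f5cf6201  benchmark_table6.tsv
a2b3c5f2097584fcbe0d7ab3454f9efc  benchmark_table7.tsv
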