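name	gene	chrom	start	end
RP24-379E2	Nes	chr3	87694297	87864718
RP23-285O8	Olig2	chr16	91182647	91321416
RP24-247A9	Pax6	chr2	105457424	105604145
RP24-245P6	PouF51	chr17	35562956	35713379
RP24-238C10	Sox1	chr8	12352075	12508633
RP24-298D8	Sox2	chr3	34443631	34605476
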