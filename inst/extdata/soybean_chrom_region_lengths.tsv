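# published per-chromosome euchromatic/heterochromatic sequence lengths (bp)
chrom	euchromatic_bp	heterochromatic_bp
Gm01	14841727	41073868
Gm02	26316426	25340287
Gm03	18879713	28901363
Gm04	18855914	30387938
Gm05	22797076	19139428
Gm06	22083366	28639455
Gm07	27609531	17073626
Gm08	31208512	15787020
Gm09	17602854	29240896
Gm10	24219274	26750361
Gm11	24367505	14805285
Gm12	17140105	22973035
Gm13	29558651	14850320
Gm14	20344958	29366246
Gm15	23378504	27560656
Gm16	17708632	19688753
Gm17	20240737	21666037
Gm18	36632197	25675943
Gm19	27373488	23215953
Gm20	17784173	28988994
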