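# neutral L-phenylalanine residue template (C9H11NO2)
name Phe
atom 1 N N -2.6917 -0.7391 -1.4706
atom 2 CA C -1.6612 -0.2683 -0.5085
atom 3 CB C -0.3563 0.0561 -1.2529
atom 4 CG C 0.8604 -0.0153 -0.3555
atom 5 CD1 C 1.4019 1.1458 0.2101
atom 6 CE1 C 2.5149 1.0722 1.0491
atom 7 CZ C 3.0977 -0.1617 1.3305
atom 8 CE2 C 2.5680 -1.3237 0.7734
atom 9 CD2 C 1.4543 -1.2522 -0.0649
atom 10 C C -2.2119 0.9525 0.2446
atom 11 OXT O -3.4336 0.7033 0.7817
atom 12 O O -1.6924 2.0436 0.4080
atom 13 H1 H -2.4373 -1.6691 -1.7991
atom 14 H2 H -3.5661 -0.8486 -0.9498
atom 15 HA H -1.4985 -1.0580 0.2351
atom 16 HB1 H -0.4092 1.0416 -1.7339
atom 17 HB2 H -0.1969 -0.6608 -2.0705
atom 18 HD11 H 0.9569 2.1180 0.0047
atom 19 HE11 H 2.9253 1.9801 1.4834
atom 20 HZ1 H 3.9649 -0.2167 1.9830
atom 21 HE21 H 3.0238 -2.2861 0.9907
atom 22 HD21 H 1.0556 -2.1687 -0.4940
atom 23 HXT H -3.6688 1.5553 1.2052
bond 1 2 1
bond 2 3 1
bond 3 4 1
bond 4 5 1
bond 5 6 1
bond 6 7 1
bond 7 8 1
bond 8 9 1
bond 2 10 1
bond 10 11 1
bond 10 12 2
bond 9 4 1
bond 1 13 1
bond 1 14 1
bond 2 15 1
bond 3 16 1
bond 3 17 1
bond 5 18 1
bond 6 19 1
bond 7 20 1
bond 8 21 1
bond 9 22 1
bond 11 23 1
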