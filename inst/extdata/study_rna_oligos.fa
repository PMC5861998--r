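>t_target biotin-tagged canonical target site RNA
AAAAAAAAGGAAGGUAAGAUCAGGGUCUCUCCA
>dtymk_offtarget biotin-tagged dtymk off-target site RNA
AAAAAAAAGGAGGUAAGAGAUCAUUUGUAGGAU
>dtymk_GtoC G-to-C point mutant of the dtymk off-target RNA
AAAAAAAAGCAGGUAAGAGAUCAUUUGUAGGAU
>scrambled scrambled control RNA
AAAAAAAAAGUUAUGGCGAGAGUGGAUAUUAGA
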