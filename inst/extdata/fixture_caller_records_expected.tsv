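mutation_id	is_indel	caller_pass	population_pass	coverage_pass	in_protected	in_public
chr1:100:A:T	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:200:C:G	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:300:G:A	FALSE	FALSE	TRUE	TRUE	FALSE	TRUE
chr1:400:T:C	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:500:A:G	FALSE	FALSE	TRUE	TRUE	FALSE	TRUE
chr1:600:C:T	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:700:G:C	FALSE	FALSE	TRUE	TRUE	FALSE	TRUE
chr1:800:T:A	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:900:A:C	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:1000:C:A	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:1100:G:T	FALSE	FALSE	TRUE	TRUE	FALSE	TRUE
chr1:1200:T:G	FALSE	TRUE	FALSE	TRUE	FALSE	TRUE
chr1:1300:A:T	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:1400:C:G	FALSE	TRUE	FALSE	TRUE	FALSE	TRUE
chr1:1500:G:A	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE
chr1:1600:T:C	FALSE	TRUE	TRUE	TRUE	TRUE	TRUE
chr1:1700:A:G	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE
chr1:1800:C:T	FALSE	TRUE	TRUE	FALSE	FALSE	TRUE
chr1:1900:G:GA	TRUE	TRUE	TRUE	TRUE	FALSE	FALSE
chr1:2000:TA:T	TRUE	TRUE	TRUE	TRUE	FALSE	FALSE
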