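individual_id	tissue	assay	call	n	approximate
IV.3	blood	direct_sanger	mixed	1	FALSE
IV.3	buccal	direct_sanger	mixed	1	FALSE
IV.1	blood	direct_sanger	mixed	1	FALSE
IV.1	buccal	direct_sanger	mixed	1	FALSE
III.2	blood	direct_sanger	mixed	1	FALSE
III.2	buccal	direct_sanger	mixed	1	FALSE
III.4	blood	direct_sanger	mixed	1	FALSE
III.4	buccal	direct_sanger	mixed	1	FALSE
IV.4	blood	direct_sanger	mixed	1	FALSE
IV.4	buccal	direct_sanger	mixed	1	FALSE
IV.5	blood	direct_sanger	mixed	1	FALSE
IV.5	buccal	direct_sanger	mixed	1	FALSE
IV.6	blood	direct_sanger	mixed	1	FALSE
IV.6	buccal	direct_sanger	mixed	1	FALSE
II.2	intestinal	direct_sanger	mixed	1	FALSE
III.6	blood	direct_sanger	major_only	1	FALSE
III.6	buccal	direct_sanger	major_only	1	FALSE
IV.7	blood	direct_sanger	major_only	1	FALSE
IV.7	buccal	direct_sanger	major_only	1	FALSE
I.2	bone	direct_sanger	major_only	1	FALSE
IV.3	blood	clone	major_only	65	TRUE
IV.3	blood	clone	minor_only	35	TRUE
IV.3	buccal	clone	major_only	96	TRUE
IV.3	buccal	clone	minor_only	4	TRUE
I.2	bone	clone	major_only	249	FALSE
III.2	pbmc	single_cell	mixed	200	TRUE
III.4	pbmc	single_cell	mixed	200	TRUE
III.6	pbmc	single_cell	major_only	200	TRUE
IV.1	pbmc	single_cell	mixed	200	TRUE
IV.3	pbmc	single_cell	mixed	200	TRUE
IV.3	thrombocyte	single_cell	major_only	113	FALSE
III.2	hair_shaft	direct_sanger	major_only	6	TRUE
III.4	hair_shaft	direct_sanger	major_only	6	TRUE
III.6	hair_shaft	direct_sanger	major_only	6	TRUE
IV.1	hair_shaft	direct_sanger	major_only	6	TRUE
IV.3	hair_shaft	direct_sanger	major_only	7	TRUE
IV.4	hair_shaft	direct_sanger	major_only	6	TRUE
IV.5	hair_shaft	direct_sanger	major_only	6	FALSE
IV.5	hair_shaft	direct_sanger	mixed	1	FALSE
IV.6	hair_shaft	direct_sanger	major_only	6	TRUE
IV.7	hair_shaft	direct_sanger	major_only	6	TRUE
III.2	hair_root	direct_sanger	mixed	5	TRUE
III.4	hair_root	direct_sanger	mixed	2	FALSE
III.4	hair_root	direct_sanger	major_only	3	FALSE
III.6	hair_root	direct_sanger	major_only	5	TRUE
IV.1	hair_root	direct_sanger	mixed	3	FALSE
IV.1	hair_root	direct_sanger	major_only	2	FALSE
IV.3	hair_root	direct_sanger	mixed	5	TRUE
IV.4	hair_root	direct_sanger	mixed	5	FALSE
IV.4	hair_root	direct_sanger	major_only	1	FALSE
IV.5	hair_root	direct_sanger	mixed	2	FALSE
IV.5	hair_root	direct_sanger	major_only	4	FALSE
IV.6	hair_root	direct_sanger	mixed	3	FALSE
IV.6	hair_root	direct_sanger	major_only	2	FALSE
IV.7	hair_root	direct_sanger	major_only	5	TRUE
III.4	rho0_fibroblast	direct_sanger	minor_only	1	FALSE
III.4	rho0_fibroblast	mps	minor_only	1	FALSE
control	blank	direct_sanger	none	1	FALSE
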