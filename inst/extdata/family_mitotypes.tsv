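sample_id	range	mitotype_string
I.1	CR	73G 146C 263G 315.1C
I.2	CR	16298C 72C 200G 263G 315.1C
II.1	CR	73G 150T 263G 315.1C
II.2	CR	16298C 72C 200G 263G 315.1C
III.1	CR	73G 195C 263G 315.1C
III.2	CR	16298C 72C 200G 263G 315.1C
III.3	CR	16093C 263G 315.1C
III.4	CR	16298C 72C 200G 263G 315.1C
III.5	CR	16224C 263G 315.1C
III.6	CR	16298C 72C 200G 263G 315.1C
IV.1	CR	16298C 72C 200G 263G 315.1C
IV.2	CR	152C 263G 315.1C 16311C
IV.3	CR	16298C 72C 200G 263G 315.1C
IV.4	CR	16298C 72C 200G 263G 315.1C
IV.5	CR	16298C 72C 200G 263G 315.1C
IV.6	CR	16298C 72C 200G 263G 315.1C
IV.7	CR	16298C 72C 200G 263G 315.1C
V.1	CR	152C 263G 315.1C 16311C
V.2	CR	152C 263G 315.1C 16311C
V.3	CR	152C 263G 315.1C 16311C
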