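id	pi3ka	mtor	is_reference
(Sa)-2	-7.9	-14.9	FALSE
(Ra)-2	-9.9	NA	FALSE
(Sa)-3	NA	-11.2	FALSE
(Ra)-3	-14.6	-11.0	FALSE
(Sa)-4	-13.4	-12.0	FALSE
(Ra)-4	-11.7	-11.5	FALSE
(Sa)-5	NA	-15.6	FALSE
(Ra)-5	-11.0	NA	FALSE
Alpelisib	-12.4	NA	TRUE
Torin 2	NA	-9.11	TRUE
PI103	-10.54	-13.35	TRUE
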