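compound	target	input	output
2	pi3ka	Sa	Sa
2	pi3ka	Ra	Ra
2	mtor	Sa	Sa
2	mtor	Ra	Sa
3	pi3ka	Sa	Ra
3	pi3ka	Ra	Ra
3	mtor	Sa	Sa
3	mtor	Ra	Ra
4	pi3ka	Sa	Sa
4	pi3ka	Ra	Ra
4	mtor	Sa	Sa
4	mtor	Ra	Ra
5	pi3ka	Sa	Ra
5	pi3ka	Ra	Ra
5	mtor	Sa	Sa
5	mtor	Ra	Sa
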