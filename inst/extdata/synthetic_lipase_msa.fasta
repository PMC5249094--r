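>dog_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>human_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>mouse_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>rat_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>cow_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>horse_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>cat_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>rabbit_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>pig_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>chicken_synthetic
MSFNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
>frog_synthetic
MSFNPLDIAKLYLVGTSTGVIKAMTDVFNQHS
>zebrafish_synthetic
--FNPLDIAKLYLVGTSTGAIKAMTDVFNQHS
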