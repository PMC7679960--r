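>xCT_demo
GMCCPKDPQIVYKTGIYFKCFCWIPWKSFQPFLSVSWTARGCGLGYCAAHHADRDARWTI
YSQWFDVMVGIEAPHYATGTIDMHVHVLFY
>homolog01
GMCCPKDCQSRLKKGICAKCVCVIWGLLFREFSNDKWTAPDGKLGYCRMNYADLDARWTI
YS-WFFFIIGIVWP-YAAGNIDMHVHVLTM
>homolog02
GVCHPADCQSCLKKGICYHCQCVIPWK-FQPQSSVSNTLRDSGCLYTRMNHADGDARWTI
VLWWFDVIVSIVKY-PW-GEIGVHVDVLEM
>homolog03
GMCCPKDFKSCYEKMICAMCQCVIPAK-FRPFSSDSWTLRDGGLGYCRHNHWDGD-RLTI
YSQWFDFTVSIYWPCMAAGEIDVHVHELTY
>homolog04
GMCCTKDCQSCYEKLIKFKCFCWIPGKCFQEQLSDKNTATDSGCGYCRHSYADGDARWPI
YSQWFDFIVGIEKPCYDTGTIDVTVQELFM
>homolog05
GMCCPKDCQSCLKTMIKAKPQCVIWWM-FQPFSSVSWYAPDCTLGYCAAHHADGD-RWTH
YSQWFDVIVGIY-P-YDAGNIDMTVHVLFM
>homolog06
GMCHPKDPQSCYKKMIKAKCFCHIWGKLIQEQSSDKWYLRGGGDLSTRHNEADLDARWTI
YLAWFFVMVSIYAPCYAAFTIDMHNQYLEY
>homolog07
GVCCPKDCLKCYRKLIKFKCFKVDPAMLLNPQSSDKWTLPGSTLGYCRHNYWDGDARWTI
YVQWTFVIVGIV-P-YA-GNLDMHVQVLFM
>homolog08
GMCLPKDFQIVY-KMIKYKCFCVIVAKLFQPFKSDFWTLPDGKDGYCRHNHWDGDARYTI
YS-WFDFMNSIEWPFYA-PTIDVHNQELEM
>homolog09
NMCCPKDPQICLKAGFYFKCFCHIWGKLFQPQKSRKWYATGGGDGYCCHNHADGDARWTI
YSWIFFFTNGIEWPFYA-FTIDVHAQELEM
>homolog10
GDCCPKDCQKVLKKGIKAKCFCWIPGKCFQPFKSDKWYLRLGTCGYCCHNHADGCAHWFI
TLQWEDIMISNYWYCYW-GNIISHADVLEM
>homolog11
ADCHPKDFQSCLKKMFCAKFFCVIPWK-LRPQLSDKWTLRDGTDGFCAHNEADGCPRWTH
YSQWFDVMVGIE-PCYAAGNIDMHVDELTA
>homolog12
GDCHFKDPQKRLKKGPYYHCFCVIPGKLLQPQSSRSWYAPDSTDESCRHHYADRD-MWPI
YLQWFHFTVGIYAVCYAAGTIIMKVQELTM
>homolog13
GDCLPFDFQKRLKTMIKAKPFCVIPWKLFREQSSDFWTLPLSGDGYCRHNHAYGDARLTI
VVQWFHFMVGIVAPCYAAGTSGMHVDELEA
>homolog14
ADFHPKDPQKCNKKGIYAKFFCVIPAK-FQPQSSVSWELPDGTLGYCRHSHEPGDDRWTI
TVQWFFIIVRIY-PFYA-FTIDSHAHVLFM
>homolog15
NDCCPKDPQSRYKKMIKAKCFKWIPGKLLQSQSSVKWTARDGTCGYCAHHYADGDARWPI
YLQIFFIIIGIYWYFYAAGELDVHVDVLEA
>homolog16
GDCHPKCPQSCNRTGIKAKCFCVIPAKLFQPFSSVSWTLRDGGCEYTCHSYWDGCARWTI
YLWWFDIIIGIEAP-MAPFNLGVHVDVLFM
>homolog17
GVCCPKDPQSCNKTGICFKCFCVIPALCFNEQSSDFWYLPGGGDLYCRHHYADGDAMWTI
TSWATDFTVGIYWP-YATGEIGVTVQELFM
>homolog18
GDFLPKDCQSVYKKMIKAHCQCVIPWKLFQPQSSVKWTKRDGKDGYCCHHHADGIARLTH
YL-WFDVMVSIEAPCYAAGELDSHVHELFM
>homolog19
ADFHFKDCLSCNKAGIKYKCVCHIPWKCFNPQSSVFWTLPDGTLGYCRMNHADGDAHWTI
VSWWFDVMVGNYWP-YATGTIGSTVHELFM
>homolog20
GVCCPKDCQICY-AGIKYKCFCVIVGK-FRPQSSDKGELPLCKCEYCAHNHADGDAHWTI
YVQWFDVIIGIEWYCMAPPNIDVHVDVLFY
>homolog21
ADCHPKDPQSCLKTMIKAMCFCVIPGK-FRSGLSDKWTAPGGGDGYCRHNYAPGDAHLTW
YSQWFFFIVGIVWPCYAAGTIGVHVHEPEM
>homolog22
NMCHPKCCQSVYKKGIYAKCQCVIPWKLFRSFSNDKWEARDGKDGYTCHSEAPRD-RWTI
YLQWFFFTVGIYWPCYATGNIDVHVQELEM
>homolog23
GMCCTADCLKCYKKMFYAKCFCWDPGKCFNPFLSVFWTAPGGTCGSCRHNHEDLDARYTI
YLQWFFFIVSIV-VCYATGNIDSHVQVLFM
>homolog24
GDKLPKDCQIVLKKMIKFKFFCWIPGMLINSQKSVKWYKRDCTLLYCRHHHADGCARWTI
YVQIFDVIVGIEAP-YAAGEIGVHVHVLEA
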