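>CON__TRYPSIN_SYNTH synthetic trypsin-like protease (autolysis source)
WYFTGLIRGQSIYASYPRSMWRPYKLHWSTITHQKTKRWNHVKYVYCGYNDDHEKIQRAL
QPEMCRFTQAKRRSRIKHLKNRHGEMAKKFQKRWWIDLINGRRHYYIIMKNTISMMKHNT
HVMNIHWYAIWNGYCNTREGRKSEITRYFRIDEHQERKRQYMNRMRSDRRIVVSVRTNEE
WCDAIIWERFRERRKKLRIICLCVRVYSAAMGDKSTMDMWLRMYDTFRKAD
>CON__LYSC_SYNTH synthetic Lys-C-like protease (autolysis source)
RFKPTKCMVKMKRMSRRLYDRFLKEKMMNIRFYLRCRWCRESRCDDVSHSKRPDRSKDKC
IDHDKENRKSSKDCWHRDFKPLKRWFGWPVHRFMYHTIIWKRHQSMDTFVKEHKKYHTWV
MKRISQYLSMGFPGNNWHFKDEKQYRKKTNSHFNTKYRKCLGAILYWMKKLGVCKPAKHR
NAIRRAEVKRSPTMKSDQLLMSKWKVAKSGWHCFSRTGKVHQGVFAQWCHKTKRGDRHCD
KWYLSNWREAMTRWSWAKKPSCVLREFR
>CON__KERATIN_SYNTH synthetic keratin-like contaminant
KRRLTRWMRWAREAFLDRADNTWTRGQKWSACAEGVKKLLRIYLRMEQADDWRQRKKWFC
EERKKFDIALEGRPKRGKKNMAWQGRSPPSIDTVPTSMDKSLFEFLSERVLSLQDTWKRS
DSNAIRQAVISDARAMIKLCIDRMTLQLDYWRYCQLSRKSDEWDTREMVTFSEKHKRRFF
HLCIYDTRRIMNRCTKQMYWSELRIEQRFDMCCHIEIHFKQRGRHDTHVVNVYYWKSDQG
CYMMYWVKEWHAKHRRAMRYYPQRKQQWVVMVKHRIKWWIYGGHKQRFGHKCHQKNFHRT
RWWRLLRLAFLRWLNINWKKMAGHKKYAKRKAVKHNNAQYKETKMMRFDTRLEFVQKMWV
YPQFRDCKRSDTCKTVQRSWMWIGEWRRKTTFSGHHWHKQ
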