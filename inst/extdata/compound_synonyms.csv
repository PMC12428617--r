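alias,canonical
valeraldehyde,pentanal
n-valeraldehyde,pentanal
n-pentanal,pentanal
n-hexanal,hexanal
n-heptanal,heptanal
n-octanal,octanal
n-nonanal,nonanal
isopropanol,isopropyl alcohol
2-propanol,isopropyl alcohol
sec-butanol,2-butanol
n-heptanol,1-heptanol
1-octene-3-ol,1-octen-3-ol
"2,6-dimethyl-4-heptanol","4-heptanol, 2,6-dimethyl-"
6-methyl-5-hepten-2-ol,"5-hepten-2-ol,6-methyl-"
(±)-6-methyl-5-hepten-2-ol,"5-hepten-2-ol,6-methyl-"
ethyl butyrate,"butanoic acid, ethyl ester"
ethyl butanoate,"butanoic acid, ethyl ester"
ethyl 2-methylbutyrate,"butanoic acid, 2-methyl-, ethyl ester"
ethyl 2-methylbutanoate,"butanoic acid, 2-methyl-, ethyl ester"
ethyl 3-methylbutyrate,"butanoic acid, 3-methyl-, ethyl ester"
ethyl isovalerate,"butanoic acid, 3-methyl-, ethyl ester"
ethyl hexanoate,"hexanoic acid, ethyl ester"
ethyl caproate,"hexanoic acid, ethyl ester"
phenethyl acetate,"acetic acid, 2-phenylethyl ester"
phenylethyl acetate,"acetic acid, 2-phenylethyl ester"
2-phenylethyl acetate,"acetic acid, 2-phenylethyl ester"
ethyl palmitate,"hexadecanoic acid, ethyl ester"
methyl octanoate,"octanoic acid, methyl ester"
methyl caprylate,"octanoic acid, methyl ester"
myristic acid,tetradecanoic acid
palmitic acid,n-hexadecanoic acid
hexadecanoic acid,n-hexadecanoic acid
1-(1h-pyrrol-2-yl)-ethanone,"ethanone, 1-(1h-pyrrol-2-yl)-"
2-acetylpyrrole,"ethanone, 1-(1h-pyrrol-2-yl)-"
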