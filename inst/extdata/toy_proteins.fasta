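>P0000001|euk_g0001
ESDATLGENGPPVPMMYSRGDTQHVLGVSRAILEPEGYAVQFLNQAATLELNLNTELTFG
NKHFPSNYGASPALEKLMHWDLSDDYPPKPLG
>P0000002|euk_g0001
ADSYFIMTTPSDLETPSQPTSVEPLQLYFIDAGANAVPVQLSVASELWYCALASTHKELM
SSAKKLKAEKLYKTITHSSKATGSSMASASA
>P0000003|euk_g0001
PSGVVEDHSNNSVKLEGNLKKFGDNWLNGARVNKTLVLYALSRYGIKDLEMGRYLAIEPT
SVHPHCDEAEAICSFRLMTRLYLPTVETLYDLRKLIKNIPQKSHFLQSARGNFSANPLYF
YTSNPTPLELFRLEDVLSTVMIRGGLSIAQQPDLRYVYITNYLALQNERTGPYPSDDLSP
SVH
>P0000004|euk_g0001
GAKLGGHYIIWVALNCCLTQLGLRRHLCPEHETNATISILGASKILRQQLLICEWEATGF
PEYHILSGANRKSGIPEIYDRSLHRLANIIIKGNYPEVKHCLSPTVILNSDVSGPEIPTT
NTDPTSNSYSAIAPRVV
>P0000005|bac_g0001
DSPAHELSATKRAAFTGVIYGTAALYIQFNGLLIVRGKFDGCLGDLLDSGEFSLAVHFGL
VYTTGKWCERIPECNKSVLEKIFIKKFAEKKKTVIRGGGSLY
>P0000006|bac_g0001
LSKAVDYIQEVAFDLSSRDSEEPYAGKIKSGRARIERKVGGGSRAKPRIASPKTKDVHYG
MQRKKGAKIFYVNGFSEPIKFLVLAGIIVKQFPQSLQLADIKSP
>P0000007|bac_g0001
ILYMVVTYKFKTQAMVFAARSDAPQLRSMYENKGRNRGIISPPVRFRVPVPELLHVQ
>P0000008|bac_g0001
SVKNEALAKGFAPTAYEANKEGIAEITFYQADRLYVEQKFDSLLGGKRMGKG
>P0000009|arc_g0001
VMQITYRRMFSKSDTIGQKINVMYIPEIYAGAEAELVCGIKLALNTGPENRELANTPEQK
ETKNV
>P0000010|arc_g0001
DNILEDMSRISIGKEIAGLTSILKELGNMAIGGICKLVMGDYWEAIGSMTGGAGEPRANT
TMLIAREKGFGALPALLQAFYESLITERQKPNMFKKTNMPEK
>P0000011|arc_g0001
INEELLSETTYAFGEASDGHDSDQEGLGTIRHVILFSAEGSFIHILPKDVTKHYSLLKGH
AKKSDVLGF
>P0000012|arc_g0001
SVSYAESQKPKILIVEKLCPLFSGLSLISAEEAQVIKSLPE
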