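"sample_id","commodity","analyte","conc_ugkg"
"S001","citrus","2,4-D",2.6
"S002","citrus","2,4-D",8.5
"S003","citrus","carbendazim",1.5
"S004","citrus","carbendazim",5.5
"S005","citrus","carbendazim",12.8
"S006","citrus","thiabendazole",2.4
"S007","citrus",,
"S008","citrus",,
"S009","citrus",,
"S010","citrus",,
"S011","citrus",,
"S012","citrus",,
"S013","citrus",,
"S014","citrus",,
"S015","citrus",,
"S016","citrus",,
"S017","citrus",,
"S018","citrus",,
"S019","citrus",,
"S020","citrus",,
"S021","apple","carbendazim",3.5
"S022","apple","carbendazim",7.2
"S023","apple",,
"S024","apple",,
"S025","apple",,
"S026","apple",,
"S027","apple",,
"S028","apple",,
"S029","apple",,
"S030","apple",,
"S031","mango",,
"S032","mango",,
"S033","mango",,
"S034","mango",,
"S035","mango",,
"S036","mango",,
"S037","mango",,
"S038","mango",,
"S039","mango",,
"S040","mango",,
"S041","lychee","carbendazim",3.1
"S042","lychee",,
"S043","lychee",,
"S044","lychee",,
"S045","lychee",,
"S046","lychee",,
"S047","lychee",,
"S048","lychee",,
"S049","lychee",,
"S050","lychee",,
"S051","lychee",,
"S052","lychee",,
"S053","lychee",,
"S054","lychee",,
"S055","lychee",,
"S056","lychee",,
"S057","lychee",,
"S058","lychee",,
"S059","lychee",,
"S060","lychee",,
"S061","tomato","carbendazim",10.6
"S062","tomato",,
"S063","tomato",,
"S064","tomato",,
"S065","tomato",,
"S066","cucumber",,
"S067","cucumber",,
"S068","cucumber",,
"S069","cucumber",,
"S070","cucumber",,
"S071","green pepper",,
"S072","green pepper",,
"S073","green pepper",,
"S074","green pepper",,
"S075","green pepper",,
"S076","green pepper",,
"S077","green pepper",,
"S078","green pepper",,
"S079","green pepper",,
"S080","green pepper",,
"S081","eggplant",,
"S082","eggplant",,
"S083","eggplant",,
"S084","eggplant",,
"S085","eggplant",,
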