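accession	phenotype	J01	S01
Jogasaki	double	117_50/117_50	250/280
Posy Bouquet Grace	double	117_50/117_50	280/280
Izunohana	double	117_50/117_50	250/280
Chikushinokaze	double	117_50/117_50	250/280
Chikushinomai	double	117_50/117_50	280/280
Chikushiruby	double	117_50/117_50	280/280
Corsage	double	117_50/117_50	280/280
Dance Party	double	117_50/117_50	280/280
Fairy Eye	double	117_50/117_50	250/280
Posy Bouquet Casey	double	117_50/117_50	250/280
Sumidanohanabi	double	167/167	236/236
Kirakiraboshi	double	167/167	236/236
HK01	double	167/167	236/236
HK02	double	167/167	236/236
03JP1	single	117_50/167	280/280
Amethyst	single	167/167	250/280
Aogashima-1	single	167/167	280/280
Blue Picotee Manaslu	single	167/167	280/280
Blue Sky	single	167/167	280/280
Bodensee	single	167/167	250/250
Chibori	single	167/167	280/280
Furau Mariko	single	167/167	250/250
Furau Yoshiko	single	167/167	280/280
Furau Yoshimi	single	167/167	250/280
Green Shadow	single	167/167	280/280
Kanuma Blue	single	167/167	250/280
Mrs. Kumiko	single	167/167	280/280
Paris	single	167/167	280/280
Peach Hime	single	167/167	280/280
Picotee	single	167/167	282/282
Ruby Red	single	167/167	280/280
Shinkai	single	167/167	280/280
Tokimeki	single	167/167	280/282
Uzuajisai	single	167/167	250/280
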