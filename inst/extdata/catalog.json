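[
  {"id": "MFH", "name": "Morphological face height", "kind": "linear", "units": "mm", "a": "n", "b": "gn"},
  {"id": "LFH", "name": "Lower facial height", "kind": "linear", "units": "mm", "a": "sn", "b": "gn"},
  {"id": "FB", "name": "Face breadth", "kind": "linear", "units": "mm", "a": "zy", "b": "zy"},
  {"id": "BB", "name": "Bigonial breadth", "kind": "linear", "units": "mm", "a": "go", "b": "go"},
  {"id": "BtW", "name": "Bitragal width", "kind": "linear", "units": "mm", "a": "tr", "b": "tr"},
  {"id": "BnW", "name": "Binocular width", "kind": "linear", "units": "mm", "a": "ec", "b": "ec"},
  {"id": "ICW", "name": "Intercanthal width", "kind": "linear", "units": "mm", "a": "en", "b": "en"},
  {"id": "OW", "name": "Ocular width", "kind": "linear", "units": "mm", "a": "en", "b": "ec"},
  {"id": "NH", "name": "Nose height", "kind": "linear", "units": "mm", "a": "n", "b": "sn"},
  {"id": "NL", "name": "Nose length", "kind": "linear", "units": "mm", "a": "n", "b": "prn"},
  {"id": "NW", "name": "Nose width", "kind": "linear", "units": "mm", "a": "al", "b": "al"},
  {"id": "ND", "name": "Nasal depth", "kind": "depth", "units": "mm", "a": "prn", "b": "sn"},
  {"id": "MW", "name": "Mouth width", "kind": "linear", "units": "mm", "a": "ch", "b": "ch"},
  {"id": "TULH", "name": "Total upper lip height", "kind": "linear", "units": "mm", "a": "sn", "b": "sto"},
  {"id": "PL", "name": "Philtrum length", "kind": "linear", "units": "mm", "a": "sn", "b": "ls"},
  {"id": "UVH", "name": "Upper vermilion height", "kind": "linear", "units": "mm", "a": "ls", "b": "sto"},
  {"id": "LVH", "name": "Lower vermilion height", "kind": "linear", "units": "mm", "a": "sto", "b": "li"},
  {"id": "UVCL", "name": "Upper vermilion curve length", "kind": "chain", "units": "mm",
   "codes": ["ls", "sto"],
   "mesh": {"section": "midsagittal", "between": ["ls", "sto"], "anchor": "ls"}},
  {"id": "LVCL", "name": "Lower vermilion curve length", "kind": "chain", "units": "mm",
   "codes": ["sto", "li"],
   "mesh": {"section": "midsagittal", "between": ["sto", "li"], "anchor": "li"}},
  {"id": "MCL", "name": "Mandible curve length", "kind": "chain", "units": "mm",
   "codes": ["go_l", "gn", "go_r"],
   "mesh": {"section": "through", "plane_through": ["go_l", "gn", "go_r"],
            "between": ["go_l", "go_r"], "anchor": "gn"}},
  {"id": "FLI", "name": "Facial length index", "kind": "index", "units": "index", "num": "MFH", "den": "FB"},
  {"id": "MFI", "name": "Mandibulo facial index", "kind": "index", "units": "index", "num": "BB", "den": "FB"},
  {"id": "II", "name": "Intercanthal index", "kind": "index", "units": "index", "num": "ICW", "den": "BnW"},
  {"id": "NLI", "name": "Nasal length index", "kind": "index", "units": "index", "num": "NH", "den": "MFH"},
  {"id": "NWI", "name": "Nasal width index", "kind": "index", "units": "index", "num": "NW", "den": "NH"},
  {"id": "LI", "name": "Labial index", "kind": "index", "units": "index", "num": ["UVH", "LVH"], "den": "MW"},
  {"id": "ULLI", "name": "Upper lip length index", "kind": "index", "units": "index", "num": "TULH", "den": "LFH"},
  {"id": "LLLI", "name": "Lower lip length index", "kind": "index", "units": "index", "num": "sto:sm", "den": "LFH"},
  {"id": "CHI", "name": "Chin height index", "kind": "index", "units": "index", "num": "sm:gn", "den": "LFH"},
  {"id": "ICI", "name": "Iridio chelial index", "kind": "index", "units": "index", "num": "ii:ch", "den": "MW"},
  {"id": "EAI", "name": "Endocanthal alar index", "kind": "index", "units": "index", "num": "ICW", "den": "NW"},
  {"id": "ACI", "name": "Alar chelial index", "kind": "index", "units": "index", "num": "NW", "den": "MW"},
  {"id": "LOTI", "name": "Labio orbital triangle index", "kind": "tri_index", "units": "index", "apex": "ls", "base": "or"},
  {"id": "NOT", "name": "Naso orbital triangle", "kind": "tri_index", "units": "index", "apex": "prn", "base": "or"},
  {"id": "NCT", "name": "Naso chelial triangle", "kind": "tri_index", "units": "index", "apex": "prn", "base": "ch"},
  {"id": "SoD", "name": "Supraorbital depth", "kind": "tragion_depth", "units": "mm", "a": "g"},
  {"id": "UFD", "name": "Upper facial depth", "kind": "tragion_depth", "units": "mm", "a": "n"},
  {"id": "OTD", "name": "Orbito tragial depth", "kind": "tragion_depth", "units": "mm", "a": "or"},
  {"id": "LTD", "name": "Labio tragial depth", "kind": "tragion_depth", "units": "mm", "a": "ls"},
  {"id": "MFD", "name": "Middle facial depth", "kind": "tragion_depth", "units": "mm", "a": "sn"},
  {"id": "SD", "name": "Sublabial depth", "kind": "tragion_depth", "units": "mm", "a": "sm"},
  {"id": "LFD", "name": "Lower facial depth", "kind": "tragion_depth", "units": "mm", "a": "gn"},
  {"id": "GTD", "name": "Gonion tragial distance", "kind": "linear", "units": "mm", "a": "go", "b": "tr"},
  {"id": "GGD", "name": "Gonion gnathion distance", "kind": "linear", "units": "mm", "a": "go", "b": "gn"},
  {"id": "LSEPD", "name": "Labiale superius Esthetic plane distance", "kind": "pdist", "units": "mm", "point": "ls", "plane": "esthetic"},
  {"id": "LIEPD", "name": "Labiale inferius Esthetic plane distance", "kind": "pdist", "units": "mm", "point": "li", "plane": "esthetic"},
  {"id": "LIE_LSE", "name": "Labiale inferius to E distance minus Labiale superius to E distance", "kind": "pdiff", "units": "mm", "a": "LIEPD", "b": "LSEPD"},
  {"id": "GTVLD", "name": "Glabella TVL distance", "kind": "pdist", "units": "mm", "point": "g", "plane": "TVL"},
  {"id": "PrTVLD", "name": "Pronasale TVL distance", "kind": "pdist", "units": "mm", "point": "prn", "plane": "TVL"},
  {"id": "PoTVLD", "name": "Pogonion TVL distance", "kind": "pdist", "units": "mm", "point": "pg", "plane": "TVL"},
  {"id": "NFrA", "name": "Nasofrontal angle", "kind": "angle", "units": "degree", "a": "g", "vertex": "n", "b": "prn"},
  {"id": "NmA", "name": "Nasomental angle", "kind": "angle", "units": "degree", "a": "n", "vertex": "prn", "b": "pg"},
  {"id": "NFA", "name": "Naso facial angle", "kind": "vangle", "units": "degree", "from1": "g", "to1": "pg", "from2": "n", "to2": "prn"},
  {"id": "CLA", "name": "Columella labial angle", "kind": "angle", "units": "degree", "a": "prn", "vertex": "sn", "b": "ls"},
  {"id": "FA", "name": "Facial angle", "kind": "angle", "units": "degree", "a": "g", "vertex": "sn", "b": "pg"},
  {"id": "PTGP", "name": "Pass transglabellar plane", "kind": "semi", "units": "mm", "level": "transglabellar"},
  {"id": "PMFP", "name": "Pass midfacial plane", "kind": "semi", "units": "mm", "level": "midfacial"},
  {"id": "PTNP", "name": "Pass transverse nasal plane", "kind": "semi", "units": "mm", "level": "transverse_nasal"}
]
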