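species_name,common_name,canopy_spread_ft,height_ft,light_requirement,breakage_resistant,site_type,allergenicity,growth_rate,transpiration_rate,leaf_area
Acer campestre,Hedge maple,46,73,full_sun,TRUE,street,low,medium,1.45,0.56
Nyssa sylvatica,Black tupelo,20,60,full_sun,FALSE,park_yard,low,medium,1.7,1.12
Liquidambar styraciflua,Sweetgum,30,47,partial,TRUE,street,high,fast,2.09,1.57
Ginkgo biloba,Ginkgo,47,69,partial,TRUE,street,medium,slow,0.62,1.04
Acer rubrum,Red maple,28,31,shade_tolerant,TRUE,street|park_yard,medium,slow,2.86,3.66
Acer saccharum,Sugar maple,46,50,partial,FALSE,street|park_yard,low,medium,1.18,3.45
Quercus rubra,Northern red oak,56,61,shade_tolerant,TRUE,street,medium,medium,2.17,2.17
Quercus palustris,Pin oak,38,71,full_sun,TRUE,street,medium,slow,1.59,2.42
Quercus bicolor,Swamp white oak,34,43,full_sun,TRUE,street,medium,medium,1.42,3.51
Tilia cordata,Littleleaf linden,54,39,full_sun,FALSE,street|park_yard,high,slow,1.26,3.44
Tilia americana,American linden,36,47,partial,FALSE,street,low,slow,2.34,1.89
Gleditsia triacanthos,Honeylocust,57,21,full_sun,FALSE,park_yard,low,slow,1.62,0.93
Ulmus americana,American elm,29,77,partial,FALSE,street,high,slow,0.81,0.67
Zelkova serrata,Japanese zelkova,47,39,partial,TRUE,street|park_yard,high,slow,2.31,1.54
Celtis occidentalis,Common hackberry,60,32,shade_tolerant,TRUE,street|park_yard,high,medium,1.63,0.59
Platanus x acerifolia,London planetree,32,56,partial,TRUE,park_yard,low,medium,3,3.04
Liriodendron tulipifera,Tulip tree,35,63,full_sun,TRUE,street,low,slow,2.32,3.05
Fagus grandifolia,American beech,23,62,full_sun,FALSE,park_yard,high,medium,2.35,0.73
Betula nigra,River birch,46,58,partial,FALSE,street,low,medium,2.08,2.09
Carpinus betulus,European hornbeam,35,46,full_sun,TRUE,park_yard,medium,medium,1.81,2.68
Carpinus caroliniana,American hornbeam,42,48,full_sun,TRUE,park_yard,medium,medium,2.51,1.75
Amelanchier canadensis,Shadblow serviceberry,42,49,shade_tolerant,TRUE,street,low,medium,1.66,3.32
Cercis canadensis,Eastern redbud,56,50,partial,TRUE,park_yard,low,slow,2.09,3.7
Cornus kousa,Kousa dogwood,25,35,full_sun,TRUE,street,low,slow,1.1,3.3
Crataegus viridis,Green hawthorn,32,66,full_sun,TRUE,park_yard,medium,fast,1.52,2.13
Syringa reticulata,Japanese tree lilac,38,68,partial,FALSE,street|park_yard,low,medium,2.02,3.24
Malus spp.,Crabapple,25,26,full_sun,TRUE,park_yard,low,slow,1.08,0.52
Prunus serrulata,Kwanzan cherry,44,31,shade_tolerant,TRUE,street|park_yard,low,medium,0.67,3.28
Pyrus calleryana,Callery pear,39,21,partial,TRUE,street|park_yard,medium,fast,2.9,2.91
Koelreuteria paniculata,Golden raintree,28,24,partial,TRUE,street,low,medium,1.76,3.2
Ostrya virginiana,American hophornbeam,49,65,shade_tolerant,FALSE,street|park_yard,high,medium,1.2,0.66
Metasequoia glyptostroboides,Dawn redwood,59,66,full_sun,FALSE,park_yard,low,fast,2.95,1.72
Taxodium distichum,Bald cypress,20,44,full_sun,FALSE,street|park_yard,low,medium,2.48,3.88
Aesculus glabra,Ohio buckeye,55,30,full_sun,TRUE,street|park_yard,medium,slow,1.67,1.62
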