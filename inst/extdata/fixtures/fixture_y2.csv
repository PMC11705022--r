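product_code,retailer_id,brand,brand_type,tra_category,container_size,container_unit,serving_size,serving_unit,price,energy_kcal,fat_g,satfat_g,carb_g,sugars_g,fibre_g,protein_g,sodium_mg,calcium_mg,fvnl_percent,year_label
P01,RA,FIXTURE,private_label_premium,C,500,g,50,g,5.71,50,1.5,0.5,7.5,2,1,2,200,25,0,2020
P02,RA,FIXTURE,private_label_discount,C,500,g,100,g,5.59,100,3,1,15,4,2,4,600,50,0,2020
P03,RA,FIXTURE,multinational,C,500,g,100,g,5.8,100,3,1,15,4,2,4,950,50,0,2020
P04,RA,FIXTURE,domestic_or_other,C,500,g,100,g,5.68,100,3,1,15,4,2,4,1200,50,0,2020
P05,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,900,50,0,2020
P06,RA,FIXTURE,multinational,C,500,g,100,g,5.77,100,3,1,35,10,2,4,80,50,0,2020
P07,RA,FIXTURE,multinational,B,500,ml,100,ml,5.65,40,0,0,10,9,0,0,10,0,0,2020
P08,RA,FIXTURE,multinational,B,500,ml,100,ml,5.53,0,0,0,0,0,0,0,0,0,0,2020
P09,RA,FIXTURE,multinational,B,500,ml,100,ml,5.74,40,0,0,10,4.4,0,0,10,0,0,2020
P10,RA,FIXTURE,multinational,B,500,ml,100,ml,5.62,40,0,0,10,4.4,0,0,10,0,0,2020
P11,RA,FIXTURE,multinational,H,500,g,100,g,5.5,720,81,50,0.6,0.6,0,0.5,600,20,0,2020
P12,RA,FIXTURE,multinational,D,500,g,100,g,5.71,400,33,21,2,1,0,25,700,800,0,2020
P13,RA,FIXTURE,multinational,D,500,g,100,g,5.59,400,33,21,2,1,0,25,700,300,0,2020
P14,RA,FIXTURE,multinational,V,500,g,100,g,5.8,30,0.3,0.1,5,3,3,2,200,40,100,2020
P15,RA,FIXTURE,multinational,C,500,g,100,g,5.68,100,3,1,15,4,2,4,80,50,0,2020
P16,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,80,50,0,2020
P17,RA,FIXTURE,multinational,C,500,g,100,g,5.77,100,3,1,15,4,2,4,80,50,0,2020
P18,RA,FIXTURE,multinational,C,500,g,100,g,5.65,100,3,1,15,4,2,4,80,50,0,2020
P19,RA,FIXTURE,multinational,C,500,g,100,g,5.53,100,3,1,15,4,2,4,80,50,0,2020
P20,RA,FIXTURE,multinational,C,500,g,100,g,5.74,100,3,1,15,4,2,4,80,50,0,2020
P21,RA,FIXTURE,multinational,C,500,g,100,g,5.62,100,3,1,15,4,2,4,80,50,0,2020
P22,RA,FIXTURE,multinational,C,500,g,100,g,5.5,100,3,1,15,4,2,4,80,50,0,2020
P23,RA,FIXTURE,multinational,C,500,g,100,g,5.71,100,3,1,15,4,2,4,80,50,0,2020
P24,RA,FIXTURE,multinational,C,500,g,100,g,5.59,100,3,1,15,4,2,4,80,50,0,2020
P25,RA,FIXTURE,multinational,C,500,g,100,g,5.8,100,3,1,15,4,2,4,80,50,0,2020
P26,RA,FIXTURE,multinational,C,500,g,100,g,5.68,100,3,1,15,4,2,4,80,50,0,2020
P27,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,80,50,0,2020
P28,RA,FIXTURE,multinational,C,500,g,100,g,5.77,100,3,1,15,4,2,4,80,50,0,2020
P29,RA,FIXTURE,multinational,C,500,g,100,g,5.65,100,3,1,15,4,2,4,80,50,0,2020
P30,RA,FIXTURE,multinational,C,500,g,100,g,5.53,100,3,1,15,4,2,4,80,50,0,2020
P31,RA,FIXTURE,multinational,C,500,g,100,g,5.74,100,3,1,15,4,2,4,80,50,0,2020
P32,RA,FIXTURE,multinational,C,500,g,100,g,5.62,100,3,1,15,4,2,4,80,50,0,2020
P33,RA,FIXTURE,multinational,C,500,g,100,g,5.5,100,3,1,15,4,2,4,80,50,0,2020
P34,RA,FIXTURE,multinational,C,500,g,100,g,5.71,100,3,1,15,4,2,4,80,50,0,2020
P35,RA,FIXTURE,multinational,C,500,g,100,g,5.59,100,3,1,15,4,2,4,80,50,0,2020
P36,RA,FIXTURE,multinational,C,500,g,100,g,5.8,100,3,1,15,4,2,4,80,50,0,2020
P37,RA,FIXTURE,multinational,C,500,g,100,g,5.68,100,3,1,15,4,2,4,80,50,0,2020
P38,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,80,50,0,2020
P39,RA,FIXTURE,multinational,C,500,g,100,g,5.77,100,3,1,15,4,2,4,80,50,0,2020
P40,RA,FIXTURE,multinational,C,500,g,100,g,5.65,100,3,1,15,4,2,4,80,50,0,2020
P41,RA,FIXTURE,multinational,C,500,g,100,g,5.53,100,3,1,15,4,2,4,80,50,0,2020
P42,RA,FIXTURE,multinational,C,500,g,100,g,5.74,100,3,1,15,4,2,4,80,50,0,2020
P43,RA,FIXTURE,multinational,C,500,g,100,g,5.62,100,3,1,15,4,2,4,80,50,0,2020
P52,RA,FIXTURE,multinational,C,500,g,100,g,5.53,100,3,1,15,4,2,4,80,50,0,2020
P44,RA,FIXTURE,multinational,C,500,g,100,g,5.5,100,3,1,15,4,"",4,80,50,0,2020
P45,RA,FIXTURE,multinational,C,500,g,100,g,5.71,100,3,1,15,4,2,4,80,50,"",2020
P46,RA,FIXTURE,multinational,D,500,g,100,g,5.59,400,33,21,2,1,0,25,700,"",0,2020
P47,RA,FIXTURE,multinational,C,500,g,100,g,5.8,100,3,1,15,4,2,4,"",50,0,2020
P48,RA,FIXTURE,multinational,C,500,g,100,g,5.68,100,3,1,15,4,2,4,80,50,0,2020
P49,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,80,50,0,2020
P50,RA,FIXTURE,multinational,C,500,g,100,g,"",100,3,1,15,4,2,4,80,50,0,2020
P51,RA,FIXTURE,multinational,C,500,g,100,g,5.65,100,3,1,15,4,2,4,80,50,0,2020
P53,RA,FIXTURE,multinational,W,500,g,100,g,5.74,100,3,1,15,4,2,4,80,50,0,2020
P54,RA,FIXTURE,multinational,X,500,g,100,g,5.62,100,3,1,15,4,2,4,80,50,0,2020
P57,RA,FIXTURE,multinational,C,500,g,100,g,5.59,100,3,1,15,4,2,4,80,50,0,2020
P58,RA,FIXTURE,multinational,C,500,g,100,g,5.8,100,3,1,15,4,2,4,80,50,0,2020
P59,RA,FIXTURE,multinational,C,450,g,100,g,5.68,100,3,1,15,4,2,4,80,50,0,2020
P60,RA,FIXTURE,multinational,C,500,g,100,g,5.56,100,3,1,15,4,2,4,80,50,0,2020
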